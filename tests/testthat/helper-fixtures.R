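## shared fixtures built in code

## tiny echogram with explicit values
tiny_echogram <- function(sv, freq = 38, t0 = "2022-04-26 06:00:00",
                          dt = 3, edge0 = 15, h = 1.5,
                          lat = NULL, lon = NULL) {
  sv <- as.matrix(sv)
  times <- as.POSIXct(t0, tz = "UTC") + dt * (seq_len(nrow(sv)) - 1L)
  echogram(sv, times, edge0 + h * (0:ncol(sv)), freq, lat = lat, lon = lon)
}

## random echogram with a controllable fraction of MISSING cells
random_echogram <- function(n_pings, n_bins, freq = 38, miss_frac = 0.1,
                            seed = 1) {
  set.seed(seed)
  sv <- matrix(stats::rnorm(n_pings * n_bins, -75, 8), n_pings, n_bins)
  sv[sample(length(sv), round(miss_frac * length(sv)))] <- NA
  tiny_echogram(sv, freq = freq)
}

## aligned 4-frequency set with constant offsets between frequencies
constant_set <- function(n_pings = 4, n_bins = 6,
                         sv38 = -75, offsets = c(`18` = -5, `38` = 0,
                                                 `70` = 2, `120` = 3)) {
  egs <- lapply(names(offsets), function(f) {
    tiny_echogram(matrix(sv38 + offsets[[f]], n_pings, n_bins),
                  freq = as.numeric(f))
  })
  align_frequencies(egs)
}

## escore model with exact binary-representable parameters
exact_model <- function(k = 2, threshold = 25) {
  mu <- matrix(c(0, 0, 0,
                 8, 8, 8)[1:(3 * k)], k, 3, byrow = TRUE)
  sigma <- matrix(0.5, k, 3)
  dimnames(mu) <- dimnames(sigma) <-
    list(paste0("class", 1:k), c("d18_38", "d70_38", "d120_38"))
  structure(list(mu = mu, sigma = sigma, threshold = threshold, k = k,
                 dominant_khz = NULL, members = NULL,
                 n_types = rep(NA_integer_, k)),
            class = "escore_model")
}

## random fitted model from a planted library
random_model <- function(seed, k = 4, sep = 12, sd = 1) {
  set.seed(seed)
  cent <- matrix(stats::runif(k * 3, -15, 10), k, 3)
  ## push centroids apart deterministically
  cent <- cent + sep * scale(matrix(seq_len(k), k, 3), center = TRUE,
                             scale = FALSE)
  lib <- planted_library(cent, n_per_class = 30, sd = sd, seed = seed)
  lib$table$class <- attr(lib, "truth")
  fit_ellipsoids(hierarchical_classify(lib, k))
}

## brute-force reference: per-cell loop classification
oracle_classify <- function(x, model, threshold = model$threshold) {
  n <- nrow(x)
  lab <- integer(n); sc <- numeric(n)
  for (i in seq_len(n)) {
    if (anyNA(x[i, ])) { lab[i] <- NA; sc[i] <- NA; next }
    s <- numeric(model$k)
    for (g in seq_len(model$k)) {
      s[g] <- sum(((x[i, ] - model$mu[g, ]) / model$sigma[g, ])^2)
    }
    m <- which.min(s)
    sc[i] <- s[m]
    lab[i] <- if (s[m] >= threshold) -1L else m
  }
  list(label = lab, escore = sc)
}

## adjusted Rand index (independent of any clustering package)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

## map planted scene class ids to model class ids (ordered by d18_38)
scene_truth_labels <- function(scene) {
  map <- order(order(scene$centroids[, 1]))
  m <- matrix(NA_integer_, nrow(scene$truth), ncol(scene$truth))
  inl <- scene$truth > 0
  m[inl] <- map[scene$truth[inl]]
  m
}

well_separated_centroids <- function() {
  matrix(c(-7, -1, -2,
           -14, -9, -13,
           6, -5, -9,
           -4, -7, -11), 4, 3, byrow = TRUE)
}
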