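#' Fit per-class ellipsoids to a labelled echo-type library
#'
#' The Escore classifier models each echo-class as an axis-aligned Gaussian
#' ellipsoid in delta-Sv space: per class k and axis j, centroid
#' `mu_kj` = mean and `sigma_kj` = sample SD of the member echo-type mean
#' triplets. SDs are floored at `sigma_floor` to keep tiny classes
#' non-degenerate.
#'
#' @param lib a labelled `echo_library` (every class non-empty).
#' @param threshold Ellipsoid-threshold: cells whose minimum Escore is `>=`
#'   this value are left unclassified (default 25).
#' @param sigma_floor minimum per-axis SD in dB (default 0.1).
#' @param dominant_khz optional named vector from [dominant_frequency()].
#' @return An object of class `escore_model` with `print`, `summary`,
#'   `coef` and `predict` methods.
#' @seealso [escore()], [classify_cells()]
#' @export
fit_ellipsoids <- function(lib, threshold = 25, sigma_floor = 0.1,
                           dominant_khz = NULL) {
  stopifnot(inherits(lib, "echo_library"))
  cl <- lib$table$class
  if (anyNA(cl)) stop_escore("library must be labelled (run hierarchical_classify)")
  if (threshold <= 0) stop_escore("threshold must be > 0")
  ks <- sort(unique(cl))
  if (!identical(ks, seq_along(ks))) stop_escore("class labels must be 1..K")
  x <- library_matrix(lib)
  mu <- t(vapply(ks, function(g) colMeans(x[cl == g, , drop = FALSE]),
                 numeric(3L)))
  sigma <- t(vapply(ks, function(g) {
    xs <- x[cl == g, , drop = FALSE]
    if (nrow(xs) < 2L) rep(0, 3L) else apply(xs, 2L, stats::sd)
  }, numeric(3L)))
  sigma <- pmax(sigma, sigma_floor)
  dimnames(mu) <- dimnames(sigma) <-
    list(paste0("class", ks), c("d18_38", "d70_38", "d120_38"))
  members <- split(lib$table$id, cl)
  structure(list(mu = mu, sigma = sigma, threshold = threshold,
                 k = length(ks), dominant_khz = dominant_khz,
                 members = members, n_types = as.integer(table(cl))),
            class = "escore_model")
}

#' Escore of a triplet against one echo-class
#'
#' The sum of squared per-axis z-scores of the triplet relative to the
#' class ellipsoid; under the class's Gaussian model it follows a
#' chi-square distribution with three degrees of freedom.
#'
#' @param triplet numeric length-3 delta-Sv triplet, or an n x 3 matrix.
#' @param k class index.
#' @param model an `escore_model`.
#' @return Non-negative Escore value(s).
#' @export
escore <- function(triplet, k, model) {
  stopifnot(inherits(model, "escore_model"))
  x <- if (is.matrix(triplet)) triplet else matrix(triplet, ncol = 3L)
  z <- sweep(sweep(x, 2L, model$mu[k, ]), 2L, model$sigma[k, ], "/")
  rowSums(z^2)
}

#' @export
print.escore_model <- function(x, ...) {
  cat(sprintf("<escore_model> %d echo-classes, Ellipsoid-threshold %g\n",
              x$k, x$threshold))
  for (g in seq_len(x$k)) {
    dom <- if (!is.null(x$dominant_khz))
      sprintf(" [%g kHz]", x$dominant_khz[[g]]) else ""
    cat(sprintf("  class %d%s (n=%d): mu = (%6.2f, %6.2f, %6.2f), sigma = (%.2f, %.2f, %.2f)\n",
                g, dom, x$n_types[g],
                x$mu[g, 1], x$mu[g, 2], x$mu[g, 3],
                x$sigma[g, 1], x$sigma[g, 2], x$sigma[g, 3]))
  }
  invisible(x)
}

#' @export
summary.escore_model <- function(object, ...) {
  print(object)
  d <- as.matrix(stats::dist(object$mu))
  diag(d) <- NA
  cat(sprintf("  min pairwise centroid distance: %.2f dB\n",
              min(d, na.rm = TRUE)))
  invisible(object)
}

#' @export
coef.escore_model <- function(object, ...) {
  cbind(object$mu, sd = object$sigma)
}

#' Classify delta-Sv cells with a fitted Escore model
#'
#' Every non-missing cell is scored against all classes; the cell is
#' assigned to the class with minimum Escore, unless that minimum is `>=`
#' the Ellipsoid-threshold, in which case it is unclassified. Ties at the
#' minimum break toward the lowest class index. MISSING propagates.
#'
#' @param grid a `delta_sv_grid` (or an n x 3 matrix of triplets).
#' @param model an `escore_model`.
#' @param threshold override of the model's Ellipsoid-threshold.
#' @return For a grid input, a `classified_grid`: lattice plus an integer
#'   `labels` matrix (1..K; -1 = unclassified; NA = MISSING) and the
#'   winning `escore` matrix. For a matrix input, a list with `label` and
#'   `escore` vectors.
#' @export
classify_cells <- function(grid, model, threshold = model$threshold) {
  stopifnot(inherits(model, "escore_model"))
  if (is.matrix(grid)) {
    return(classify_triplets(grid, model, threshold))
  }
  stopifnot(inherits(grid, "delta_sv_grid"))
  a <- as.vector(grid$d18_38)
  x <- cbind(a, as.vector(grid$d70_38), as.vector(grid$d120_38))
  res <- classify_triplets(x, model, threshold)
  dims <- dim(grid$d18_38)
  structure(list(ping_times = grid$ping_times, lat = grid$lat,
                 lon = grid$lon, depth_edges = grid$depth_edges,
                 labels = matrix(res$label, dims[1], dims[2]),
                 escore = matrix(res$escore, dims[1], dims[2]),
                 k = model$k, threshold = threshold),
            class = "classified_grid")
}

classify_triplets <- function(x, model, threshold) {
  n <- nrow(x)
  scores <- matrix(Inf, n, model$k)
  ok <- stats::complete.cases(x)
  for (g in seq_len(model$k)) {
    scores[ok, g] <- escore(x[ok, , drop = FALSE], g, model)
  }
  label <- rep(NA_integer_, n)
  sc <- rep(NA_real_, n)
  if (any(ok)) {
    best <- max.col(-scores[ok, , drop = FALSE], ties.method = "first")
    bs <- scores[ok, , drop = FALSE][cbind(seq_len(sum(ok)), best)]
    lab <- ifelse(bs >= threshold, -1L, best)
    label[ok] <- lab
    sc[ok] <- bs
  }
  list(label = label, escore = sc)
}

#' @rdname classify_cells
#' @param object an `escore_model`.
#' @param newdata a `delta_sv_grid` or n x 3 matrix.
#' @param ... passed on (e.g. `threshold`).
#' @export
predict.escore_model <- function(object, newdata, ...) {
  classify_cells(newdata, object, ...)
}

#' @export
print.classified_grid <- function(x, ...) {
  lab <- x$labels
  n_eval <- sum(!is.na(lab))
  cat(sprintf("<classified_grid> %d pings x %d bins; %d evaluable cells\n",
              nrow(lab), ncol(lab), n_eval))
  tab <- table(factor(lab[!is.na(lab)], levels = c(seq_len(x$k), -1L)))
  for (g in seq_len(x$k)) {
    cat(sprintf("  class %d: %5.1f%%\n", g, 100 * tab[[g]] / max(n_eval, 1)))
  }
  cat(sprintf("  unclassified: %5.1f%%\n",
              100 * tab[[as.character(-1)]] / max(n_eval, 1)))
  invisible(x)
}

#' Ellipsoid-threshold sensitivity sweep
#'
#' On a training grid with known truth labels, sweeps the
#' Ellipsoid-threshold and reports, per threshold, the percentage of
#' evaluable cells well-classified (assigned to the truth class),
#' mis-classified (assigned to another class) and not classified, both by
#' cell count and weighted by each cell's linear sA contribution.
#'
#' @param grid a `delta_sv_grid`.
#' @param truth integer matrix of truth labels aligned with `grid`
#'   (`NA` cells and cells with truth `-1` are excluded from evaluation).
#' @param model an `escore_model`.
#' @param thresholds thresholds to sweep (default `1:100`, which includes
#'   the operating default 25).
#' @param sa_weights optional non-negative per-cell weight matrix (e.g.
#'   linear sv * bin thickness) for the sA-weighted percentages.
#' @return A `sensitivity_table` data frame.
#' @export
sensitivity_sweep <- function(grid, truth, model, thresholds = 1:100,
                              sa_weights = NULL) {
  stopifnot(inherits(grid, "delta_sv_grid"))
  a <- as.vector(grid$d18_38)
  x <- cbind(a, as.vector(grid$d70_38), as.vector(grid$d120_38))
  tr <- as.vector(truth)
  keep <- stats::complete.cases(x) & !is.na(tr) & tr > 0L
  if (!any(keep)) stop_escore("empty truth set")
  x <- x[keep, , drop = FALSE]
  tr <- tr[keep]
  w <- if (is.null(sa_weights)) rep(1, sum(keep)) else as.vector(sa_weights)[keep]
  scores <- vapply(seq_len(model$k), function(g) escore(x, g, model),
                   numeric(nrow(x)))
  best <- max.col(-scores, ties.method = "first")
  bs <- scores[cbind(seq_len(nrow(scores)), best)]
  out <- lapply(thresholds, function(th) {
    lab <- ifelse(bs >= th, -1L, best)
    well <- lab == tr
    mis <- lab != tr & lab > 0L
    notc <- lab == -1L
    data.frame(threshold = th,
               pct_well = 100 * mean(well),
               pct_mis = 100 * mean(mis),
               pct_not = 100 * mean(notc),
               pct_sa_well = 100 * sum(w[well]) / sum(w),
               pct_sa_mis = 100 * sum(w[mis]) / sum(w),
               pct_sa_not = 100 * sum(w[notc]) / sum(w))
  })
  structure(do.call(rbind, out),
            class = c("sensitivity_table", "data.frame"))
}

#' Per-class echograms
#'
#' For each echo-class, an echogram at the requested frequency with Sv
#' masked to that class's cells (all other cells MISSING), restricted to a
#' depth window (default 15-250 m). Class index 0 returns the unclassified
#' mask.
#'
#' @param classified a `classified_grid`.
#' @param set the aligned `echogram_set`.
#' @param frequency_khz frequency whose Sv is masked.
#' @param depth_window length-2 depth window in m.
#' @return Named list of [echogram] objects (`class1`, ..., `unclassified`).
#' @export
per_class_echograms <- function(classified, set, frequency_khz,
                                depth_window = c(15, 250)) {
  stopifnot(inherits(classified, "classified_grid"),
            inherits(set, "echogram_set"))
  key <- as.character(round(frequency_khz))
  if (!key %in% names(set$sv)) stop_escore("frequency not in set")
  if (!isTRUE(all.equal(classified$depth_edges, set$depth_edges)) ||
      length(classified$ping_times) != length(set$ping_times)) {
    stop_escore("classified grid and echogram set lattices differ",
                class = "escore_alignment_error")
  }
  tops <- set$depth_edges[-length(set$depth_edges)]
  bots <- set$depth_edges[-1]
  keep <- which(tops >= depth_window[1] - 1e-9 & bots <= depth_window[2] + 1e-9)
  edges <- set$depth_edges[c(keep, max(keep) + 1L)]
  sv <- set$sv[[key]][, keep, drop = FALSE]
  lab <- classified$labels[, keep, drop = FALSE]
  targets <- c(seq_len(classified$k), -1L)
  out <- lapply(targets, function(g) {
    m <- sv
    m[is.na(lab) | lab != g] <- NA_real_
    echogram(m, set$ping_times, edges, as.numeric(frequency_khz),
             lat = set$lat, lon = set$lon)
  })
  names(out) <- c(paste0("class", seq_len(classified$k)), "unclassified")
  out
}

#' Write / read an Escore model as JSON
#'
#' Format: `{"classes": [{"id", "mu": [3], "sigma": [3], "dominant_khz"}],
#' "threshold": t}`.
#' @param model an `escore_model`.
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  classes <- lapply(seq_len(model$k), function(g) {
    list(id = g, mu = as.numeric(model$mu[g, ]),
         sigma = as.numeric(model$sigma[g, ]),
         dominant_khz = if (is.null(model$dominant_khz)) NULL
                        else as.numeric(model$dominant_khz[[g]]))
  })
  jsonlite::write_json(list(classes = classes, threshold = model$threshold),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  k <- length(obj$classes)
  mu <- t(vapply(obj$classes, function(cl) as.numeric(unlist(cl$mu)),
                 numeric(3L)))
  sigma <- t(vapply(obj$classes, function(cl) as.numeric(unlist(cl$sigma)),
                    numeric(3L)))
  dom <- vapply(obj$classes,
                function(cl) as.numeric(cl$dominant_khz %||% NA), 1.0)
  dimnames(mu) <- dimnames(sigma) <-
    list(paste0("class", seq_len(k)), c("d18_38", "d70_38", "d120_38"))
  structure(list(mu = mu, sigma = sigma,
                 threshold = as.numeric(obj$threshold), k = k,
                 dominant_khz = if (all(is.na(dom))) NULL else dom,
                 members = NULL, n_types = rep(NA_integer_, k)),
            class = "escore_model")
}

#' Serialize a classified grid in the Sv CSV dialect
#'
#' Integer labels; `-1` = unclassified, empty field = MISSING.
#' @param classified a `classified_grid`.
#' @param path output path.
#' @export
write_classified_csv <- function(classified, path) {
  e <- classified$depth_edges
  cols <- sprintf("d_%s_%s", fmt_depth(e[-length(e)]), fmt_depth(e[-1]))
  header <- paste(c("ping_time", "lat", "lon", cols), collapse = ",")
  lab <- classified$labels
  n <- nrow(lab)
  vals <- matrix("", n, ncol(lab))
  ok <- !is.na(lab)
  vals[ok] <- sprintf("%d", lab[ok])
  lat <- classified$lat %||% rep(NA_real_, n)
  lon <- classified$lon %||% rep(NA_real_, n)
  tstr <- format(classified$ping_times, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  pos <- cbind(ifelse(is.na(lat), "", sprintf("%.6f", lat)),
               ifelse(is.na(lon), "", sprintf("%.6f", lon)))
  writeLines(c(header, apply(cbind(tstr, pos, vals), 1L, paste,
                             collapse = ",")), path)
  invisible(path)
}
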