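#' Specify a synthetic scattering layer
#'
#' A layer occupies one depth band by day and (possibly) another by night --
#' a step-change diel vertical migration -- and carries a per-frequency mean
#' Sv signature with Gaussian dB noise. `class` is the truth echo-class
#' identity planted in the scene.
#'
#' @param class integer truth class.
#' @param day_band,night_band length-2 depth bands (m), within [0, 250].
#' @param mean_sv named numeric vector of mean Sv (dB) per frequency, e.g.
#'   `c("18" = -83, "38" = -76, "70" = -77, "120" = -78)`.
#' @param noise_sd per-cell Gaussian Sv noise SD, dB (per frequency,
#'   independent draws).
#' @param occupancy probability a cell inside the band is occupied.
#' @param n_patches number of contiguous horizontal patches; each patch's
#'   mean Sv is jittered by `patch_sd` (echo-type-level variability).
#' @param patch_sd patch-mean jitter SD, dB.
#' @export
layer_spec <- function(class, day_band, night_band = day_band,
                       mean_sv, noise_sd = 0.5, occupancy = 1,
                       n_patches = 20L, patch_sd = 0.5) {
  if (max(day_band, night_band) > 250 || min(day_band, night_band) < 0) {
    stop_escore("layer bands must lie within [0, 250] m")
  }
  if (noise_sd < 0) stop_escore("noise_sd must be >= 0")
  if (occupancy <= 0 || occupancy > 1) stop_escore("occupancy in (0, 1]")
  structure(list(class = as.integer(class), day_band = day_band,
                 night_band = night_band, mean_sv = mean_sv,
                 noise_sd = noise_sd, occupancy = occupancy,
                 n_patches = as.integer(n_patches), patch_sd = patch_sd),
            class = "layer_spec")
}

#' Specify a synthetic multifrequency scene
#'
#' @param n_esdu number of ESDU pings (3-ping ESDUs on the output lattice).
#' @param esdu_interval_s seconds per ESDU (3 pings x ping interval).
#' @param start_time scene start (POSIXct UTC or ISO string).
#' @param lat,lon track position (fixed) for solar geometry.
#' @param depth_edges vertical lattice (m); default 15 to 250.5 m at 1.5 m.
#' @param layers list of [layer_spec]s; earlier layers win cell overlaps.
#' @param background_sv named per-frequency background Sv (dB).
#' @param background_noise_sd background Sv noise SD (dB).
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @export
scene_spec <- function(n_esdu = 9600L, esdu_interval_s = 9,
                       start_time = "2022-04-26T00:00:00Z",
                       lat = -16.5, lon = 41.5,
                       depth_edges = seq(15, by = 1.5, length.out = 158L),
                       layers = list(),
                       background_sv = c(`18` = -95, `38` = -95,
                                         `70` = -95, `120` = -95),
                       background_noise_sd = 0.5,
                       seed = 1L) {
  if (is.character(start_time)) {
    start_time <- as.POSIXct(start_time, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%OSZ")
  }
  structure(list(n_esdu = as.integer(n_esdu),
                 esdu_interval_s = esdu_interval_s, start_time = start_time,
                 lat = lat, lon = lon, depth_edges = depth_edges,
                 layers = layers, background_sv = background_sv,
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate a synthetic multifrequency scene
#'
#' Builds an aligned four-frequency (18/38/70/120 kHz) ESDU echogram set
#' with planted layers, truth labels and truth ROIs. For each cell, Sv(f) is
#' the owning layer's mean (plus its patch jitter) plus Gaussian noise when
#' the cell lies in the layer's solar-period-dependent band and the
#' occupancy draw succeeds; otherwise background. Layers use their day band
#' during day and sunrise (organisms descend at dawn) and their night band
#' during sunset and night. Overlaps go to the earliest-declared layer.
#' Truth ROIs are emitted per layer patch: the longest ping run of the patch
#' lying in a single solar period, provided it spans at least `min_roi_esdu`
#' ESDUs.
#'
#' @param spec a [scene_spec].
#' @param min_roi_esdu minimum ROI width in ESDUs (default 30).
#' @return list with `set` (`echogram_set`), `truth` (integer label matrix;
#'   -1 = background), `rois` (list of [roi]), `periods` (solar period per
#'   ESDU), `centroids` (planted delta-Sv class centroids), and `spec`.
#' @export
generate_scene <- function(spec, min_roi_esdu = 30L) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  freqs <- names(spec$background_sv)
  n <- spec$n_esdu
  edges <- spec$depth_edges
  nb <- length(edges) - 1L
  tops <- edges[-length(edges)]
  times <- spec$start_time + spec$esdu_interval_s * (0:(n - 1L))
  periods <- classify_solar(times, spec$lat, spec$lon)
  use_day_band <- periods %in% c("day", "sunrise")

  sv <- lapply(freqs, function(f) {
    matrix(stats::rnorm(n * nb, spec$background_sv[[f]],
                        spec$background_noise_sd), n, nb)
  })
  names(sv) <- freqs
  truth <- matrix(-1L, n, nb)
  claimed <- matrix(FALSE, n, nb)
  rois <- list()

  for (li in seq_along(spec$layers)) {
    ly <- spec$layers[[li]]
    patch_of <- pmin(ly$n_patches,
                     1L + (seq_len(n) - 1L) %/% ceiling(n / ly$n_patches))
    jit <- matrix(stats::rnorm(ly$n_patches * length(freqs), 0, ly$patch_sd),
                  ly$n_patches, length(freqs), dimnames = list(NULL, freqs))
    for (p in seq_len(ly$n_patches)) {
      pings <- which(patch_of == p)
      if (length(pings) == 0L) next
      for (ping in pings) {
        band <- if (use_day_band[ping]) ly$day_band else ly$night_band
        bins <- which(tops >= band[1] - 1e-9 & tops < band[2] - 1e-9)
        bins <- bins[!claimed[ping, bins]]
        if (length(bins) == 0L) next
        occ <- if (ly$occupancy >= 1) rep(TRUE, length(bins)) else
          stats::runif(length(bins)) < ly$occupancy
        bins <- bins[occ]
        if (length(bins) == 0L) next
        for (f in freqs) {
          sv[[f]][ping, bins] <- ly$mean_sv[[f]] + jit[p, f] +
            stats::rnorm(length(bins), 0, ly$noise_sd)
        }
        claimed[ping, bins] <- TRUE
        truth[ping, bins] <- ly$class
      }
      ## truth ROI: longest single-period run within the patch
      runs <- rle(as.character(periods[pings]))
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      best <- which.max(runs$lengths)
      if (runs$lengths[best] >= min_roi_esdu) {
        sel <- pings[starts[best]:ends[best]]
        band <- if (use_day_band[sel[1L]]) ly$day_band else ly$night_band
        if (band[2] <= 250) {
          rois[[length(rois) + 1L]] <- roi(
            id = sprintf("L%d_P%d", li, p),
            ping_start = sel[1L] - 1L, ping_end = sel[length(sel)],
            depth_top = band[1], depth_bottom = band[2])
        }
      }
    }
  }
  egs <- lapply(freqs, function(f) {
    echogram(sv[[f]], times, edges, as.numeric(f),
             lat = rep(spec$lat, n), lon = rep(spec$lon, n))
  })
  set <- align_frequencies(egs)
  cents <- t(vapply(spec$layers, function(ly) {
    c(ly$mean_sv[["18"]] - ly$mean_sv[["38"]],
      ly$mean_sv[["70"]] - ly$mean_sv[["38"]],
      ly$mean_sv[["120"]] - ly$mean_sv[["38"]])
  }, numeric(3L)))
  dimnames(cents) <- list(
    paste0("class", vapply(spec$layers, `[[`, 1L, "class")),
    c("d18_38", "d70_38", "d120_38"))
  list(set = set, truth = truth, rois = rois, periods = periods,
       centroids = cents, spec = spec)
}

#' Canonical four-layer scene
#'
#' The package's reference study conditions: a 24 h fixed-position track in
#' the Mozambique Channel (16.5 S, 41.5 E, late April) sampled at one
#' 3-ping ESDU per 9 s on a 1.5 m lattice from 15 to 250.5 m, with four
#' non-overlapping scattering layers whose delta-Sv signatures mimic the
#' qualitative frequency-response ordering of the four echo-classes: class 3
#' is 18-kHz dominant with a decreasing response, classes 1, 2 and 4 peak at
#' 38 kHz with distinct high-frequency slopes. Layers 1 and 3 migrate
#' vertically between day and night; pairwise centroid separation is at
#' least 10 dB, about six combined noise SDs.
#'
#' @param seed RNG seed.
#' @param n_esdu scene width; the default covers a full diel cycle.
#' @return A [scene_spec].
#' @export
canonical_scene <- function(seed = 1L, n_esdu = 9600L) {
  layers <- list(
    layer_spec(1L, day_band = c(80, 120), night_band = c(50, 80),
               mean_sv = c(`18` = -83, `38` = -76, `70` = -77, `120` = -78)),
    layer_spec(2L, day_band = c(140, 170), night_band = c(140, 170),
               mean_sv = c(`18` = -86, `38` = -72, `70` = -81, `120` = -85)),
    layer_spec(3L, day_band = c(185, 235), night_band = c(90, 130),
               mean_sv = c(`18` = -70, `38` = -76, `70` = -81, `120` = -85)),
    layer_spec(4L, day_band = c(20, 45), night_band = c(20, 45),
               mean_sv = c(`18` = -78, `38` = -74, `70` = -81, `120` = -85)))
  scene_spec(n_esdu = n_esdu, layers = layers, seed = seed)
}

#' Planted-partition echo-type library
#'
#' Synthetic library for classifier and cluster-validation tests: `K`
#' Gaussian blobs of echo-type mean triplets around given centroids.
#'
#' @param centroids K x 3 matrix of class centroids (delta-Sv, dB).
#' @param n_per_class echo-types per class.
#' @param sd within-class SD per axis (dB).
#' @param seed RNG seed.
#' @return An unlabeled `echo_library` with a `truth` attribute (planted
#'   class per echo-type).
#' @export
planted_library <- function(centroids, n_per_class = 50L, sd = 1,
                            seed = 1L) {
  set.seed(seed)
  k <- nrow(centroids)
  ets <- list(); truth <- integer(0)
  for (g in seq_len(k)) {
    for (i in seq_len(n_per_class)) {
      tp <- matrix(stats::rnorm(3, centroids[g, ], sd), 1L, 3L,
                   dimnames = list(NULL, c("d18_38", "d70_38", "d120_38")))
      ets[[length(ets) + 1L]] <- structure(
        list(id = sprintf("c%d_%d", g, i), roi_id = NA,
             ping = 1L, bin = 1L, triplets = tp,
             mean_triplet = tp[1L, ]),
        class = "echo_type")
      truth <- c(truth, g)
    }
  }
  lib <- build_library(ets)
  attr(lib, "truth") <- truth
  lib
}
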