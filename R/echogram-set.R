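#' Align echo-integrated echograms across frequencies
#'
#' Places a list of single-frequency ESDU echograms onto one shared lattice.
#' Ping times must match exactly across frequencies (no interpolation across
#' pings); the vertical lattices must share bin size and phase. The shared
#' depth axis is the union of the per-frequency ranges: cells outside a
#' frequency's own range are MISSING for that frequency, so per-frequency
#' depth limits are preserved and any joint (all-frequency) analysis is
#' automatically restricted to the intersection.
#'
#' @param echograms list of [echogram] objects, one per frequency.
#' @param time_tol_s tolerance (s) for ping-time agreement; default 0 means
#'   exact match on the shared ping index.
#' @return An `echogram_set`: list with `frequencies`, shared `ping_times`,
#'   `lat`, `lon`, `depth_edges`, and `sv` (a named list of matrices).
#' @export
align_frequencies <- function(echograms, time_tol_s = 0.5) {
  stopifnot(length(echograms) >= 1L,
            all(vapply(echograms, inherits, TRUE, "echogram")))
  freqs <- vapply(echograms, function(e) e$frequency_khz, 1.0)
  if (anyDuplicated(freqs)) stop_escore("duplicate frequency keys")
  names(echograms) <- as.character(round(freqs))
  ref <- echograms[[1L]]
  n <- length(ref$ping_times)
  for (e in echograms) {
    if (length(e$ping_times) != n ||
        max(abs(as.numeric(e$ping_times) - as.numeric(ref$ping_times))) >
        time_tol_s) {
      stop_escore("ping-time mismatch beyond tolerance between frequencies",
                  class = "escore_alignment_error")
    }
  }
  ## shared vertical lattice: same step, same phase
  steps <- vapply(echograms, function(e) diff(e$depth_edges)[1L], 1.0)
  if (any(vapply(echograms,
                 function(e) any(abs(diff(e$depth_edges) - steps[1]) > 1e-6),
                 TRUE)) || any(abs(steps - steps[1]) > 1e-6)) {
    stop_escore("frequencies are not on a common uniform vertical lattice",
                class = "escore_alignment_error")
  }
  h <- steps[[1L]]
  tops <- vapply(echograms, function(e) e$depth_edges[1L], 1.0)
  phase <- (tops - tops[1]) / h
  if (any(abs(phase - round(phase)) > 1e-6)) {
    stop_escore("vertical lattices have incompatible phase",
                class = "escore_alignment_error")
  }
  lo <- min(tops)
  hi <- max(vapply(echograms, function(e) max(e$depth_edges), 1.0))
  nb <- round((hi - lo) / h)
  edges <- lo + h * (0:nb)
  sv <- lapply(echograms, function(e) {
    m <- matrix(NA_real_, n, nb)
    off <- round((e$depth_edges[1L] - lo) / h)
    m[, off + seq_len(ncol(e$sv))] <- e$sv
    m
  })
  structure(list(frequencies = as.numeric(freqs),
                 ping_times = ref$ping_times,
                 lat = ref$lat, lon = ref$lon,
                 depth_edges = edges, sv = sv),
            class = "echogram_set")
}

#' @export
print.echogram_set <- function(x, ...) {
  cat(sprintf("<echogram_set> %s kHz: %d pings x %d depth bins (%.1f-%.1f m)\n",
              paste(x$frequencies, collapse = "/"),
              length(x$ping_times), length(x$depth_edges) - 1L,
              min(x$depth_edges), max(x$depth_edges)))
  invisible(x)
}

#' Extract one frequency from an echogram set as an echogram
#' @param set an `echogram_set`.
#' @param frequency_khz frequency to extract.
#' @export
set_echogram <- function(set, frequency_khz) {
  key <- as.character(round(frequency_khz))
  if (!key %in% names(set$sv)) stop_escore("frequency ", key, " not in set")
  echogram(set$sv[[key]], set$ping_times, set$depth_edges,
           frequency_khz, lat = set$lat, lon = set$lon)
}
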