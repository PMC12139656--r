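#' Convert volume backscattering strength to the linear domain
#'
#' @param sv_db Sv in dB re 1 m-1. `NA` propagates.
#' @return Linear sv (m-1).
#' @keywords internal
db_to_linear <- function(sv_db) 10^(sv_db / 10)

#' Convert linear sv to dB
#'
#' Zero or negative linear values map to `NA` (below any representable dB).
#' @param sv_lin linear sv.
#' @keywords internal
linear_to_db <- function(sv_lin) {
  out <- rep(NA_real_, length(sv_lin))
  ok <- !is.na(sv_lin) & sv_lin > 0
  out[ok] <- 10 * log10(sv_lin[ok])
  out
}

## 4 * pi * 1852^2: scales depth-integrated linear backscatter (the area
## backscattering coefficient, m2 m-2) to NASC in m2 nmi-2.
NASC_SCALE <- 4 * pi * 1852^2

stop_escore <- function(..., class = "escore_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
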