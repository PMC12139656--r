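#' Construct an echogram
#'
#' An echogram is a single-frequency time x depth grid of volume
#' backscattering strength Sv (dB re 1 m-1). Rows are pings, columns are
#' depth bins; `NA` marks MISSING cells. Depth is positive down and bins are
#' half-open intervals `[top, bottom)`.
#'
#' @param sv numeric matrix, `n_pings x n_bins`, Sv in dB; `NA` = MISSING.
#' @param ping_times `POSIXct` vector (UTC), non-decreasing, length `n_pings`.
#' @param depth_edges strictly increasing numeric vector of bin boundaries
#'   (m), length `n_bins + 1`.
#' @param frequency_khz acoustic frequency in kHz.
#' @param lat,lon optional per-ping positions in decimal degrees.
#' @return An object of class `echogram`.
#' @export
echogram <- function(sv, ping_times, depth_edges, frequency_khz,
                     lat = NULL, lon = NULL) {
  sv <- as.matrix(sv)
  storage.mode(sv) <- "double"
  if (!inherits(ping_times, "POSIXct")) {
    ping_times <- as.POSIXct(ping_times, tz = "UTC")
  }
  attr(ping_times, "tzone") <- "UTC"
  depth_edges <- as.numeric(depth_edges)
  if (length(ping_times) != nrow(sv)) {
    stop_escore("ping_times length (", length(ping_times),
                ") != number of ping rows (", nrow(sv), ")")
  }
  if (length(depth_edges) != ncol(sv) + 1L) {
    stop_escore("depth_edges must have n_bins + 1 entries")
  }
  if (any(diff(depth_edges) <= 0)) {
    stop_escore("depth_edges must be strictly increasing",
                class = "escore_validation_error")
  }
  if (is.unsorted(ping_times)) {
    stop_escore("ping_times must be non-decreasing",
                class = "escore_validation_error")
  }
  if (any(!is.na(sv) & !is.finite(sv))) {
    stop_escore("non-missing Sv must be finite",
                class = "escore_validation_error")
  }
  if (!is.null(lat) && length(lat) != nrow(sv)) {
    stop_escore("lat must have one value per ping")
  }
  if (!is.null(lon) && length(lon) != nrow(sv)) {
    stop_escore("lon must have one value per ping")
  }
  structure(
    list(sv = sv, ping_times = ping_times, depth_edges = depth_edges,
         frequency_khz = as.numeric(frequency_khz),
         lat = if (is.null(lat)) NULL else as.numeric(lat),
         lon = if (is.null(lon)) NULL else as.numeric(lon)),
    class = "echogram")
}

#' @export
print.echogram <- function(x, ...) {
  cat(sprintf("<echogram> %g kHz: %d pings x %d depth bins (%.1f-%.1f m)\n",
              x$frequency_khz, nrow(x$sv), ncol(x$sv),
              min(x$depth_edges), max(x$depth_edges)))
  rng <- range(x$sv, na.rm = TRUE)
  cat(sprintf("  Sv range %.1f to %.1f dB; %.1f%% missing\n",
              rng[1], rng[2], 100 * mean(is.na(x$sv))))
  invisible(x)
}

#' @export
dim.echogram <- function(x) dim(x$sv)

## depth bin midpoints
depth_mids <- function(eg) {
  e <- eg$depth_edges
  (e[-length(e)] + e[-1]) / 2
}

fmt_depth <- function(x) sprintf("%.1f", x)

#' Write an echogram to the Sv CSV dialect
#'
#' One row per ping, header `ping_time,lat,lon,d_<top>_<bottom>,...` with
#' depth column names in metres at 0.1 m precision. Empty fields mark
#' MISSING cells. Sv values are written at a fixed precision (`digits`
#' decimal places) so that write -> read -> write round-trips byte-exactly.
#'
#' @param eg an [echogram].
#' @param path output file path.
#' @param digits decimal places for Sv values (default 6).
#' @export
write_sv_csv <- function(eg, path, digits = 6L) {
  e <- eg$depth_edges
  cols <- sprintf("d_%s_%s", fmt_depth(e[-length(e)]), fmt_depth(e[-1]))
  header <- paste(c("ping_time", "lat", "lon", cols), collapse = ",")
  n <- nrow(eg$sv)
  lat <- eg$lat %||% rep(NA_real_, n)
  lon <- eg$lon %||% rep(NA_real_, n)
  fmt <- paste0("%.", digits, "f")
  val <- matrix("", n, ncol(eg$sv))
  ok <- !is.na(eg$sv)
  val[ok] <- sprintf(fmt, eg$sv[ok])
  tstr <- format(eg$ping_times, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  pos <- cbind(ifelse(is.na(lat), "", sprintf("%.6f", lat)),
               ifelse(is.na(lon), "", sprintf("%.6f", lon)))
  body <- apply(cbind(tstr, pos, val), 1L, paste, collapse = ",")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an echogram from the Sv CSV dialect
#'
#' @param path input file path.
#' @param frequency_khz frequency to stamp on the echogram (kHz).
#' @return An [echogram]. Unparseable or empty Sv fields become MISSING.
#' @export
read_sv_csv <- function(path, frequency_khz) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop_escore("empty Sv CSV: ", path,
                                      class = "escore_format_error")
  hdr <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  if (length(hdr) < 4L || !identical(hdr[1:3], c("ping_time", "lat", "lon"))) {
    stop_escore("malformed Sv CSV header in ", path,
                class = "escore_format_error")
  }
  dcols <- hdr[-(1:3)]
  m <- regmatches(dcols, regexec("^d_([0-9.+-]+)_([0-9.+-]+)$", dcols))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop_escore("malformed depth column name(s): ",
                            paste(dcols[bad], collapse = ", "),
                            class = "escore_format_error")
  tops <- vapply(m, function(z) as.numeric(z[2]), 1.0)
  bots <- vapply(m, function(z) as.numeric(z[3]), 1.0)
  edges <- c(tops, bots[length(bots)])
  if (any(abs(bots[-length(bots)] - tops[-1]) > 1e-6) || any(diff(edges) <= 0)) {
    stop_escore("depth columns not contiguous/monotone in ", path,
                class = "escore_validation_error")
  }
  body <- lines[-1L]
  parts <- strsplit(body, ",", fixed = TRUE)
  nb <- length(dcols)
  nf <- nb + 3L
  sv <- matrix(NA_real_, length(body), nb)
  lat <- lon <- rep(NA_real_, length(body))
  times <- rep(as.POSIXct(NA), length(body))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    length(p) <- nf                      # trailing empty fields
    times[i] <- as.POSIXct(p[1], tz = "UTC", format = "%Y-%m-%dT%H:%M:%OSZ")
    lat[i] <- suppressWarnings(as.numeric(p[2]))
    lon[i] <- suppressWarnings(as.numeric(p[3]))
    sv[i, ] <- suppressWarnings(as.numeric(p[-(1:3)]))
  }
  if (anyNA(times)) stop_escore("unparseable ping_time in ", path,
                                class = "escore_format_error")
  if (all(is.na(lat))) lat <- NULL
  if (all(is.na(lon))) lon <- NULL
  echogram(sv, times, edges, frequency_khz, lat = lat, lon = lon)
}

#' Echo-integration configuration
#'
#' Defaults follow standard narrowband survey processing: ESDU of 3 pings
#' by 1.5 m, a -100 dB integration threshold, the top 15 m excluded, and
#' per-frequency maximum echo-integrated depths (18 kHz: 1000 m, 38: 800,
#' 70: 500, 120: 250, 200: 120).
#'
#' @param esdu_pings pings per ESDU (>= 1).
#' @param vertical_bin_m ESDU vertical extent (m, > 0).
#' @param sv_threshold_db samples below this Sv contribute zero linear
#'   energy to the cell mean.
#' @param surface_exclusion_m bins whose top edge is shallower than this are
#'   dropped.
#' @param max_depth_m named numeric vector of per-frequency (kHz) maximum
#'   depths (m).
#' @return A list of class `integration_config`.
#' @export
integration_config <- function(esdu_pings = 3L, vertical_bin_m = 1.5,
                               sv_threshold_db = -100,
                               surface_exclusion_m = 15,
                               max_depth_m = c(`18` = 1000, `38` = 800,
                                               `70` = 500, `120` = 250,
                                               `200` = 120)) {
  esdu_pings <- as.integer(esdu_pings)
  if (esdu_pings < 1L) stop_escore("esdu_pings must be >= 1")
  if (vertical_bin_m <= 0) stop_escore("vertical_bin_m must be > 0")
  if (surface_exclusion_m < 0) stop_escore("surface_exclusion_m must be >= 0")
  structure(list(esdu_pings = esdu_pings, vertical_bin_m = vertical_bin_m,
                 sv_threshold_db = sv_threshold_db,
                 surface_exclusion_m = surface_exclusion_m,
                 max_depth_m = max_depth_m),
            class = "integration_config")
}

#' Echo-integrate a raw echogram onto the ESDU lattice
#'
#' Each ESDU cell is the linear-domain mean of its constituent raw samples,
#' log-transformed back to dB: `10*log10(mean(sv_linear))`. Samples below
#' the integration threshold contribute zero linear energy but still count
#' in the denominator; MISSING samples are excluded from both. A cell whose
#' linear sum is zero (all samples missing or thresholded) is MISSING.
#' Vertical resampling uses proportional overlap of raw bins with target
#' bins, so raw lattices that are not an exact multiple of the ESDU bin are
#' handled without truncation. After integration, bins with top edge above
#' the surface exclusion and bins extending below the frequency's maximum
#' depth are removed.
#'
#' @param raw an [echogram] on a lattice at least as fine as the ESDU.
#' @param config an [integration_config].
#' @return An [echogram] on the ESDU lattice (ping time and position of an
#'   ESDU = those of its first ping).
#' @export
echo_integrate <- function(raw, config = integration_config()) {
  stopifnot(inherits(raw, "echogram"), inherits(config, "integration_config"))
  lin <- db_to_linear(raw$sv)
  lin[!is.na(raw$sv) & raw$sv < config$sv_threshold_db] <- 0

  ## vertical: proportional-overlap aggregation onto bins of vertical_bin_m
  re <- raw$depth_edges
  h <- config$vertical_bin_m
  n_t <- ceiling((max(re) - min(re)) / h - 1e-9)
  te <- min(re) + h * (0:n_t)
  nb_raw <- ncol(raw$sv)
  ## overlap weight matrix nb_raw x n_t (sparse in practice; loop columns)
  wsum <- matrix(0, nrow(raw$sv), n_t)   # sum of weighted linear sv
  wtot <- matrix(0, nrow(raw$sv), n_t)   # sum of weights over non-missing
  miss <- is.na(lin)
  lin0 <- ifelse(miss, 0, lin)
  for (j in seq_len(nb_raw)) {
    top <- re[j]; bot <- re[j + 1L]
    j0 <- max(1L, findInterval(top + 1e-12, te))
    j1 <- min(n_t, findInterval(bot - 1e-12, te))
    for (t in j0:j1) {
      ov <- min(bot, te[t + 1L]) - max(top, te[t])
      if (ov <= 0) next
      wsum[, t] <- wsum[, t] + ov * lin0[, j]
      wtot[, t] <- wtot[, t] + ov * !miss[, j]
    }
  }
  ## horizontal: group pings into ESDUs of esdu_pings (trailing partial
  ## kept); the cell is the pooled thickness-weighted linear mean over all
  ## constituent non-missing samples
  np <- nrow(wsum)
  g <- (seq_len(np) - 1L) %/% config$esdu_pings + 1L
  ng <- max(g)
  cell <- matrix(NA_real_, ng, n_t)
  for (gi in seq_len(ng)) {
    rows <- which(g == gi)
    s <- colSums(wsum[rows, , drop = FALSE])
    w <- colSums(wtot[rows, , drop = FALSE])
    cell[gi, ] <- ifelse(w > 0, s / pmax(w, .Machine$double.xmin), NA_real_)
  }
  first <- match(seq_len(ng), g)
  sv_out <- matrix(linear_to_db(cell), ng, n_t)

  ## depth trimming: surface exclusion and per-frequency max depth
  keep <- te[-length(te)] >= config$surface_exclusion_m - 1e-9
  fk <- as.character(round(raw$frequency_khz))
  if (fk %in% names(config$max_depth_m)) {
    keep <- keep & te[-1] <= config$max_depth_m[[fk]] + 1e-9
  }
  if (!any(keep)) stop_escore("no depth bins remain after exclusion")
  kidx <- which(keep)
  edges_out <- te[c(kidx, max(kidx) + 1L)]
  if (any(diff(kidx) != 1L)) stop_escore("non-contiguous depth retention")
  echogram(sv_out[, kidx, drop = FALSE],
           raw$ping_times[first], edges_out, raw$frequency_khz,
           lat = raw$lat[first], lon = raw$lon[first])
}

#' Nautical area scattering coefficient per ping
#'
#' NASC (sA, m2 nmi-2) over a half-open depth interval:
#' `4*pi*1852^2 * sum(10^(Sv/10) * bin_thickness)` across non-missing bins
#' whose top edge lies in `[depth_from, depth_to)`. All-missing selections
#' yield 0 (empty sum).
#'
#' @param eg an [echogram].
#' @param depth_from,depth_to depth interval (m), `depth_from < depth_to`.
#' @return Numeric vector of sA per ping.
#' @export
sv_to_nasc <- function(eg, depth_from, depth_to) {
  stopifnot(inherits(eg, "echogram"))
  if (!(depth_from < depth_to)) stop_escore("depth_from must be < depth_to")
  e <- eg$depth_edges
  tops <- e[-length(e)]
  sel <- tops >= depth_from - 1e-9 & tops < depth_to - 1e-9
  if (!any(sel)) stop_escore("empty depth selection [", depth_from, ", ",
                             depth_to, ")")
  thick <- diff(e)[sel]
  lin <- db_to_linear(eg$sv[, sel, drop = FALSE])
  lin[is.na(lin)] <- 0
  as.numeric(NASC_SCALE * (lin %*% thick))
}
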