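#' Per-cell Sv differences relative to 38 kHz
#'
#' The classification feature space: per echo-integration cell the triplet
#' (Sv18 - Sv38, Sv70 - Sv38, Sv120 - Sv38) in dB. A cell's triplet is
#' MISSING iff any of the four contributing frequencies is MISSING there.
#'
#' @param set an `echogram_set` containing 18, 38, 70 and 120 kHz.
#' @return A `delta_sv_grid`: lattice metadata plus matrices `d18_38`,
#'   `d70_38`, `d120_38` (NA = MISSING, jointly).
#' @export
compute_delta_sv <- function(set) {
  stopifnot(inherits(set, "echogram_set"))
  need <- c("18", "38", "70", "120")
  if (!"38" %in% names(set$sv)) {
    stop_escore("38 kHz reference frequency missing from set")
  }
  if (!all(need %in% names(set$sv))) {
    stop_escore("delta-Sv needs 18, 38, 70 and 120 kHz; missing: ",
                paste(setdiff(need, names(set$sv)), collapse = ", "))
  }
  ref <- set$sv[["38"]]
  miss <- is.na(set$sv[["18"]]) | is.na(ref) |
          is.na(set$sv[["70"]]) | is.na(set$sv[["120"]])
  d <- lapply(c("18", "70", "120"), function(k) {
    m <- set$sv[[k]] - ref
    m[miss] <- NA_real_
    m
  })
  structure(list(ping_times = set$ping_times, lat = set$lat, lon = set$lon,
                 depth_edges = set$depth_edges,
                 d18_38 = d[[1L]], d70_38 = d[[2L]], d120_38 = d[[3L]]),
            class = "delta_sv_grid")
}

#' @export
print.delta_sv_grid <- function(x, ...) {
  cat(sprintf("<delta_sv_grid> %d pings x %d bins; %.1f%% missing\n",
              nrow(x$d18_38), ncol(x$d18_38), 100 * mean(is.na(x$d18_38))))
  invisible(x)
}

## n x 3 matrix of triplets for non-missing cells, with cell coordinates
delta_cells <- function(grid, rows = NULL, cols = NULL) {
  rows <- rows %||% seq_len(nrow(grid$d18_38))
  cols <- cols %||% seq_len(ncol(grid$d18_38))
  a <- grid$d18_38[rows, cols, drop = FALSE]
  b <- grid$d70_38[rows, cols, drop = FALSE]
  c3 <- grid$d120_38[rows, cols, drop = FALSE]
  ok <- which(!is.na(a), arr.ind = TRUE)
  list(triplets = cbind(d18_38 = a[!is.na(a)], d70_38 = b[!is.na(a)],
                        d120_38 = c3[!is.na(a)]),
       ping = rows[ok[, 1L]], bin = cols[ok[, 2L]])
}

#' Serialize a delta-Sv grid to CSV
#'
#' Same dialect as the Sv CSV but with three value columns per depth bin,
#' suffixed `_d18_38`, `_d70_38`, `_d120_38`.
#' @param grid a `delta_sv_grid`.
#' @param path output path.
#' @param digits decimal places.
#' @export
write_delta_csv <- function(grid, path, digits = 6L) {
  e <- grid$depth_edges
  base <- sprintf("d_%s_%s", fmt_depth(e[-length(e)]), fmt_depth(e[-1]))
  cols <- as.vector(t(outer(base, c("_d18_38", "_d70_38", "_d120_38"),
                            paste0)))
  header <- paste(c("ping_time", "lat", "lon", cols), collapse = ",")
  n <- nrow(grid$d18_38); nb <- ncol(grid$d18_38)
  fmt <- paste0("%.", digits, "f")
  vals <- matrix("", n, 3L * nb)
  for (j in seq_len(nb)) {
    for (k in 1:3) {
      v <- grid[[c("d18_38", "d70_38", "d120_38")[k]]][, j]
      vals[, 3L * (j - 1L) + k] <- ifelse(is.na(v), "", sprintf(fmt, v))
    }
  }
  lat <- grid$lat %||% rep(NA_real_, n)
  lon <- grid$lon %||% rep(NA_real_, n)
  tstr <- format(grid$ping_times, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  pos <- cbind(ifelse(is.na(lat), "", sprintf("%.6f", lat)),
               ifelse(is.na(lon), "", sprintf("%.6f", lon)))
  writeLines(c(header, apply(cbind(tstr, pos, vals), 1L, paste,
                             collapse = ",")), path)
  invisible(path)
}

#' Read a delta-Sv grid from CSV
#' @param path file written by [write_delta_csv()].
#' @export
read_delta_csv <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  if (length(hdr) < 6L || !identical(hdr[1:3], c("ping_time", "lat", "lon"))) {
    stop_escore("malformed delta CSV header", class = "escore_format_error")
  }
  dc <- hdr[-(1:3)]
  m <- regmatches(dc, regexec("^d_([0-9.+-]+)_([0-9.+-]+)_(d18_38|d70_38|d120_38)$", dc))
  if (any(vapply(m, length, 1L) != 4L)) {
    stop_escore("malformed delta column names", class = "escore_format_error")
  }
  tops <- vapply(m, function(z) as.numeric(z[2]), 1.0)
  bots <- vapply(m, function(z) as.numeric(z[3]), 1.0)
  utops <- tops[seq(1, length(tops), by = 3)]
  ubots <- bots[seq(1, length(bots), by = 3)]
  edges <- c(utops, ubots[length(ubots)])
  body <- lines[-1L]
  parts <- strsplit(body, ",", fixed = TRUE)
  nb <- length(utops)
  d18 <- d70 <- d120 <- matrix(NA_real_, length(body), nb)
  lat <- lon <- rep(NA_real_, length(body))
  times <- rep(as.POSIXct(NA), length(body))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    length(p) <- 3L + 3L * nb
    times[i] <- as.POSIXct(p[1], tz = "UTC", format = "%Y-%m-%dT%H:%M:%OSZ")
    lat[i] <- suppressWarnings(as.numeric(p[2]))
    lon[i] <- suppressWarnings(as.numeric(p[3]))
    v <- suppressWarnings(as.numeric(p[-(1:3)]))
    d18[i, ] <- v[seq(1, 3 * nb, by = 3)]
    d70[i, ] <- v[seq(2, 3 * nb, by = 3)]
    d120[i, ] <- v[seq(3, 3 * nb, by = 3)]
  }
  structure(list(ping_times = times,
                 lat = if (all(is.na(lat))) NULL else lat,
                 lon = if (all(is.na(lon))) NULL else lon,
                 depth_edges = edges,
                 d18_38 = d18, d70_38 = d70, d120_38 = d120),
            class = "delta_sv_grid")
}

#' RGB composite echogram
#'
#' Maps three frequencies to red/green/blue channels by linearly rescaling
#' Sv from `display_range` to [0, 1] with clipping; MISSING renders as 0.
#' Conventional triples are 18/38/70 kHz (18 -> red) and 38/70/120 kHz
#' (38 -> red).
#'
#' @param set an `echogram_set`.
#' @param frequency_triple numeric length-3 vector, mapped to (R, G, B).
#' @param display_range length-2 `(low, high)` Sv display range in dB.
#' @return An `rgb_composite`: array `n_pings x n_bins x 3` in [0, 1] plus
#'   the channel mapping and range.
#' @export
rgb_composite <- function(set, frequency_triple = c(18, 38, 70),
                          display_range = c(-90, -50)) {
  stopifnot(inherits(set, "echogram_set"), length(frequency_triple) == 3L)
  if (display_range[1] >= display_range[2]) {
    stop_escore("degenerate display_range (low >= high)")
  }
  keys <- as.character(round(frequency_triple))
  if (!all(keys %in% names(set$sv))) {
    stop_escore("frequencies not in set: ",
                paste(setdiff(keys, names(set$sv)), collapse = ", "))
  }
  img <- array(0, c(nrow(set$sv[[1L]]), ncol(set$sv[[1L]]), 3L))
  for (k in 1:3) {
    v <- (set$sv[[keys[k]]] - display_range[1]) / diff(display_range)
    v[is.na(v)] <- 0
    img[, , k] <- pmin(1, pmax(0, v))
  }
  structure(list(image = img, frequency_triple = frequency_triple,
                 display_range = display_range,
                 ping_times = set$ping_times, depth_edges = set$depth_edges),
            class = "rgb_composite")
}

#' Export an RGB composite as PNG
#'
#' Written with pings on the x axis and depth increasing downward.
#' @param comp an `rgb_composite`.
#' @param path output PNG path.
#' @export
write_composite_png <- function(comp, path) {
  stopifnot(inherits(comp, "rgb_composite"))
  ## image is pings x bins x 3; PNG wants rows = depth (top first)
  img <- aperm(comp$image, c(2L, 1L, 3L))
  png::writePNG(img, path)
  invisible(path)
}
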