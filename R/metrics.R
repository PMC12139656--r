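#' Read zone labels from CSV
#'
#' Columns `start_iso,end_iso,zone`; intervals are half-open
#' `[start, end)` and must not overlap. Zone labels are consumed as input
#' (e.g. AC, C, TZ, mix); `mix` pings are excluded from metrics.
#'
#' @param path CSV path.
#' @return data frame with POSIXct `start`, `end` and character `zone`.
#' @export
read_zone_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_iso", "end_iso", "zone")
  if (!all(need %in% names(df))) {
    stop_escore("zone CSV needs columns ", paste(need, collapse = ","),
                class = "escore_format_error")
  }
  out <- data.frame(
    start = as.POSIXct(df$start_iso, tz = "UTC",
                       format = "%Y-%m-%dT%H:%M:%OSZ"),
    end = as.POSIXct(df$end_iso, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OSZ"),
    zone = df$zone, stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end)) {
    stop_escore("unparseable zone timestamps", class = "escore_format_error")
  }
  o <- order(out$start)
  out <- out[o, ]
  if (any(out$end[-nrow(out)] > out$start[-1] + 1e-6)) {
    stop_escore("zone intervals overlap", class = "escore_validation_error")
  }
  out
}

#' Assign a zone label to each ping time
#' @param times POSIXct vector.
#' @param zones data frame from [read_zone_csv()].
#' @return character vector (NA where no zone covers the time).
#' @export
assign_zones <- function(times, zones) {
  t <- as.numeric(times)
  out <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(zones))) {
    sel <- t >= as.numeric(zones$start[i]) & t < as.numeric(zones$end[i])
    out[sel] <- zones$zone[i]
  }
  out
}

#' Total area backscatter per ping subset
#'
#' Total sA: the sum of per-depth-bin sA from the surface exclusion depth to
#' the frequency's maximum echo-integrated depth, per ping, restricted to
#' pings of a given solar period and zone, then summarized as mean +/- SD
#' across pings.
#'
#' @param eg an echo-integrated [echogram].
#' @param periods factor from [classify_solar()], one per ping.
#' @param zones character zone label per ping.
#' @param period,zone the period/zone to select (`NULL` = no restriction).
#' @return list with per-ping `sa`, `mean`, `sd`, `n_pings`; `n_pings = 0`
#'   flags an empty selection.
#' @export
total_sa <- function(eg, periods = NULL, zones = NULL, period = NULL,
                     zone = NULL) {
  stopifnot(inherits(eg, "echogram"))
  sel <- rep(TRUE, nrow(eg$sv))
  if (!is.null(period)) {
    if (is.null(periods)) stop_escore("periods required to filter by period")
    sel <- sel & as.character(periods) == period
  }
  if (!is.null(zone)) {
    if (is.null(zones)) stop_escore("zones required to filter by zone")
    sel <- sel & !is.na(zones) & zones == zone
  }
  sel[is.na(sel)] <- FALSE
  sa <- sv_to_nasc(eg, min(eg$depth_edges), max(eg$depth_edges) + 1e-9)
  sa <- sa[sel]
  list(sa = sa, mean = if (length(sa)) mean(sa) else NA_real_,
       sd = if (length(sa) > 1) stats::sd(sa) else NA_real_,
       n_pings = length(sa))
}

#' Diel vertical migration strength
#'
#' `1 - sA_meso_night / sA_meso_day`, where the mesopelagic sA integrates
#' from 200 m to the maximum echo-integrated depth. Used at 18, 38 and
#' 70 kHz (the frequencies that reach below 200 m with margin). Undefined
#' (NA) when the daytime mesopelagic sA is zero.
#'
#' @param sa_meso_day,sa_meso_night mesopelagic area backscatter, day/night.
#' @return DVM strength (dimensionless).
#' @export
dvm_strength <- function(sa_meso_day, sa_meso_night) {
  ifelse(sa_meso_day > 0, 1 - sa_meso_night / sa_meso_day, NA_real_)
}

#' Mesopelagic sA of an echogram subset
#'
#' Convenience wrapper: summed sA over `[200, max depth)` averaged across
#' the selected pings.
#' @inheritParams total_sa
#' @param depth_from mesopelagic upper bound (m), default 200.
#' @export
meso_sa <- function(eg, periods = NULL, period = NULL, depth_from = 200) {
  sel <- if (is.null(period)) rep(TRUE, nrow(eg$sv)) else
    as.character(periods) == period
  sel[is.na(sel)] <- FALSE
  if (!any(sel)) return(NA_real_)
  sa <- sv_to_nasc(eg, depth_from, max(eg$depth_edges) + 1e-9)
  mean(sa[sel])
}

#' NASC by depth category
#'
#' Splits the water column into surface (15-200 m), intermediate
#' (200-400 m) and deep (400 m to the maximum echo-integrated depth)
#' categories and sums NASC in each, per ping subset. For 120 kHz only
#' surface and intermediate exist; for 200 kHz only surface (range limits).
#'
#' @inheritParams total_sa
#' @return Named list of mean NASC per category over the selected pings.
#' @export
depth_category_nasc <- function(eg, periods = NULL, zones = NULL,
                                period = NULL, zone = NULL) {
  stopifnot(inherits(eg, "echogram"))
  sel <- rep(TRUE, nrow(eg$sv))
  if (!is.null(period)) sel <- sel & as.character(periods) == period
  if (!is.null(zone)) sel <- sel & !is.na(zones) & zones == zone
  sel[is.na(sel)] <- FALSE
  maxd <- max(eg$depth_edges)
  f <- round(eg$frequency_khz)
  cats <- list(surface = c(15, min(200, maxd)))
  if (f < 200 && maxd > 200) cats$intermediate <- c(200, min(400, maxd))
  if (f < 120 && maxd > 400) cats$deep <- c(400, maxd + 1e-9)
  out <- lapply(cats, function(b) {
    sa <- sv_to_nasc(eg, b[1], b[2])
    if (any(sel)) mean(sa[sel]) else NA_real_
  })
  out
}

#' Eddy kinetic energy
#'
#' `EKE = (u^2 + v^2) / 2` element-wise over current components (m s-1),
#' a proxy for mesoscale dynamics.
#'
#' @param u,v east/north velocity components, m s-1 (vectors or matrices).
#' @return EKE in m2 s-2, same shape as the inputs.
#' @export
eke <- function(u, v) {
  if (any(!is.finite(u)) || any(!is.finite(v))) {
    stop_escore("velocities must be finite")
  }
  (u^2 + v^2) / 2
}

#' Metrics report across frequencies, zones and periods
#'
#' Assembles total sA (mean +/- SD across pings) per (frequency, zone,
#' period), DVM strength per frequency (18/38/70 kHz only), and
#' depth-category NASC per (frequency, zone, period). Sunrise/sunset pings
#' are excluded (only day and night feed the metrics).
#'
#' @param egs named list of echo-integrated [echogram]s keyed by frequency.
#' @param periods factor from [classify_solar()], one per ping.
#' @param zones character zone label per ping (`"mix"` and `NA` excluded).
#' @return A `metrics_report`: list of data frames `total_sa`, `dvm`,
#'   `depth_nasc`.
#' @export
metrics_report <- function(egs, periods, zones = NULL) {
  zs <- if (is.null(zones)) "all" else setdiff(unique(stats::na.omit(zones)),
                                               "mix")
  rows <- list(); drows <- list(); nrows <- list()
  for (fk in names(egs)) {
    eg <- egs[[fk]]
    for (z in zs) {
      zarg <- if (is.null(zones)) NULL else z
      for (p in c("day", "night")) {
        ts <- total_sa(eg, periods, zones, period = p, zone = zarg)
        rows[[length(rows) + 1L]] <- data.frame(
          frequency_khz = as.numeric(fk), zone = z, period = p,
          mean_sa = ts$mean, sd_sa = ts$sd, n_pings = ts$n_pings)
        nc <- depth_category_nasc(eg, periods, zones, period = p, zone = zarg)
        for (cat in names(nc)) {
          nrows[[length(nrows) + 1L]] <- data.frame(
            frequency_khz = as.numeric(fk), zone = z, period = p,
            category = cat, nasc = nc[[cat]])
        }
      }
    }
    if (as.numeric(fk) %in% c(18, 38, 70)) {
      d <- meso_sa(eg, periods, "day")
      n <- meso_sa(eg, periods, "night")
      drows[[length(drows) + 1L]] <- data.frame(
        frequency_khz = as.numeric(fk), sa_meso_day = d, sa_meso_night = n,
        dvm_strength = dvm_strength(d, n))
    }
  }
  structure(list(total_sa = do.call(rbind, rows),
                 dvm = do.call(rbind, drows),
                 depth_nasc = do.call(rbind, nrows)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n  total sA (mean per ping):\n")
  print(utils::head(x$total_sa, 12L), row.names = FALSE)
  cat("  DVM strength:\n")
  print(x$dvm, row.names = FALSE)
  invisible(x)
}
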