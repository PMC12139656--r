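#' Solar elevation angle
#'
#' Low-precision solar ephemeris (NOAA-style: mean solar anomaly, ecliptic
#' longitude, declination and equation of time), accurate to about 0.1-0.2
#' degrees over recent decades -- ample for day/night banding.
#'
#' @param time `POSIXct` (UTC).
#' @param lat,lon position in decimal degrees.
#' @return Solar elevation above the horizon, degrees.
#' @export
solar_elevation <- function(time, lat, lon) {
  if (any(!is.finite(lat)) || any(abs(lat) > 90)) {
    stop_escore("latitude must be finite and within [-90, 90]")
  }
  if (any(!is.finite(lon))) stop_escore("longitude must be finite")
  t <- as.numeric(as.POSIXct(time, tz = "UTC"))
  if (any(is.na(t))) stop_escore("invalid time")
  d2r <- pi / 180
  ## days since J2000.0
  n <- (t - 946728000) / 86400
  L <- (280.460 + 0.9856474 * n) %% 360        # mean longitude
  g <- ((357.528 + 0.9856003 * n) %% 360) * d2r # mean anomaly
  lambda <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * d2r # ecliptic lon
  eps <- (23.439 - 4e-7 * n) * d2r             # obliquity
  alpha <- atan2(cos(eps) * sin(lambda), cos(lambda)) / d2r # right ascension
  delta <- asin(sin(eps) * sin(lambda))        # declination (rad)
  ## equation of time (minutes): mean solar time - apparent
  eqt <- 4 * (((L - alpha) + 180) %% 360 - 180)
  ## true solar time in degrees of hour angle
  utc_hours <- (t %% 86400) / 3600
  tst <- (utc_hours * 60 + eqt + 4 * lon) %% 1440
  ha <- (tst / 4 - 180) * d2r
  el <- asin(sin(lat * d2r) * sin(delta) +
             cos(lat * d2r) * cos(delta) * cos(ha)) / d2r
  el
}

#' Classify the solar period of a ping
#'
#' Four periods from solar elevation: `day` above +6 degrees, `night` below
#' -6 degrees, and the +/-6 degree twilight band split into `sunrise` (sun
#' ascending) and `sunset` (sun descending).
#'
#' @param time `POSIXct` (UTC); vectorized.
#' @param lat,lon position in decimal degrees (recycled to `length(time)`).
#' @param band half-width of the twilight band in degrees of elevation.
#' @return factor with levels `night`, `sunrise`, `day`, `sunset`.
#' @export
classify_solar <- function(time, lat, lon, band = 6) {
  n <- length(time)
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  el <- solar_elevation(time, lat, lon)
  el2 <- solar_elevation(as.POSIXct(time, tz = "UTC") + 60, lat, lon)
  out <- ifelse(el > band, "day",
         ifelse(el < -band, "night",
         ifelse(el2 >= el, "sunrise", "sunset")))
  factor(out, levels = c("night", "sunrise", "day", "sunset"))
}
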