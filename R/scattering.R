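#' Mackenzie sound speed in seawater
#'
#' Nine-term Mackenzie (1981) polynomial in temperature, salinity and depth.
#' Valid for roughly T in [-2, 35] degC, S in [25, 40], D in [0, 8000] m;
#' inputs outside that envelope trigger a warning.
#'
#' @param T_c temperature, degC.
#' @param S salinity, PSU.
#' @param D depth, m.
#' @return Sound speed, m s-1.
#' @export
mackenzie_sound_speed <- function(T_c, S, D) {
  if (any(!is.finite(c(T_c, S, D)))) stop_escore("non-finite input")
  if (any(T_c < -2 | T_c > 35) || any(S < 25 | S > 40) ||
      any(D < 0 | D > 8000)) {
    warning("input outside the Mackenzie validity envelope")
  }
  1448.96 + 4.591 * T_c - 5.304e-2 * T_c^2 + 2.374e-4 * T_c^3 +
    1.340 * (S - 35) + 1.630e-2 * D + 1.675e-7 * D^2 -
    1.025e-2 * T_c * (S - 35) - 7.139e-13 * T_c * D^3
}

#' Acoustic medium at depth
#'
#' @param temperature_c water temperature, degC.
#' @param salinity salinity, PSU.
#' @param depth_m depth, m.
#' @param density water density, kg m-3.
#' @param atm_pa atmospheric pressure, Pa.
#' @return A `medium`: sound speed (Mackenzie), density, ambient pressure
#'   (atmospheric + hydrostatic).
#' @export
medium <- function(temperature_c = 26, salinity = 35.5, depth_m = 25,
                   density = 1025, atm_pa = 101325) {
  c_ms <- mackenzie_sound_speed(temperature_c, salinity, depth_m)
  structure(list(temperature_c = temperature_c, salinity = salinity,
                 depth_m = depth_m, c = c_ms, rho = density,
                 pressure_pa = atm_pa + density * 9.81 * depth_m),
            class = "medium")
}

#' Scattering model specification
#'
#' Forward-model parameters for one candidate organism. Size is given either
#' as equivalent spherical radius (`esr_mm`) or body length (`length_mm`);
#' for elongated shapes the two are related volume-preservingly through the
#' length-to-width ratio (`lw_ratio = L / 2a`).
#'
#' @param name label.
#' @param family one of `dwba_bent_cylinder`, `fluid_bent_cylinder_random`,
#'   `highpass_fluid_sphere`, `gas_bubble_spherical`, `gas_bubble_ellipsoid`,
#'   `hybrid_gas_body`.
#' @param esr_mm equivalent spherical radius, mm.
#' @param length_mm body length, mm.
#' @param g,h density and sound-speed contrasts (body relative to water).
#' @param lw_ratio length-to-width ratio (>= 1).
#' @param orient_mean_deg,orient_sd_deg Gaussian orientation distribution
#'   (degrees from broadside) for the DWBA cylinder.
#' @param aspect prolate aspect ratio for ellipsoid bubbles.
#' @param gamma ratio of specific heats of the gas.
#' @param gas_esr_mm gas-inclusion ESR for the hybrid family; defaults to a
#'   5 % gas volume fraction of the body.
#' @export
scatter_spec <- function(name, family, esr_mm = NA, length_mm = NA,
                         g = 1.04, h = 1.04, lw_ratio = 4,
                         orient_mean_deg = 0, orient_sd_deg = 20,
                         aspect = 1, gamma = 1.4, gas_esr_mm = NA) {
  families <- c("dwba_bent_cylinder", "fluid_bent_cylinder_random",
                "highpass_fluid_sphere", "gas_bubble_spherical",
                "gas_bubble_ellipsoid", "hybrid_gas_body")
  if (!family %in% families) stop_escore("unknown model family: ", family)
  if (is.na(esr_mm) && is.na(length_mm)) stop_escore("need esr_mm or length_mm")
  if (!is.na(esr_mm) && esr_mm <= 0) stop_escore("esr_mm must be > 0")
  if (!is.na(length_mm) && length_mm <= 0) stop_escore("length_mm must be > 0")
  if (g <= 0 || h <= 0) stop_escore("g and h must be > 0")
  if (lw_ratio < 1) stop_escore("lw_ratio must be >= 1")
  structure(list(name = name, family = family, esr_mm = esr_mm,
                 length_mm = length_mm, g = g, h = h, lw_ratio = lw_ratio,
                 orient_mean_deg = orient_mean_deg,
                 orient_sd_deg = orient_sd_deg, aspect = aspect,
                 gamma = gamma, gas_esr_mm = gas_esr_mm),
            class = "scatter_spec")
}

## cylinder geometry (radius a, length L, both m) from spec, volume-
## preserving when only ESR is given: pi a^2 L = (4/3) pi esr^3
cylinder_geometry <- function(spec) {
  r <- spec$lw_ratio
  if (!is.na(spec$length_mm)) {
    L <- spec$length_mm * 1e-3
    a <- L / (2 * r)
  } else {
    esr <- spec$esr_mm * 1e-3
    a <- esr * (2 / (3 * r))^(1 / 3)
    L <- 2 * a * r
  }
  list(a = a, L = L)
}

## Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
gauss_legendre <- function(n) {
  if (n == 1L) return(list(x = 0, w = 2))
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1L, ]^2))
}

## DWBA backscattering cross-section of a uniformly bent cylinder at a
## single tilt angle theta (radians from broadside), weak-scatterer kernel:
## f_bs = (k1/4) \int a (gk - gr) [J1(2 k2 a cos beta)/cos beta]
##        exp(2 i k2 . r) ds
dwba_sigma_at_tilt <- function(k1, a, L, g, h, theta, n_seg = 60L) {
  gk <- (1 - g * h^2) / (g * h^2)
  gr <- (g - 1) / g
  if (gk == 0 && gr == 0) return(0)
  k2 <- k1 / h
  rho_c <- 3 * L                      # radius of curvature
  half <- L / (2 * rho_c)             # arc half-angle
  phi <- seq(-half, half, length.out = n_seg)
  ds <- rho_c * (phi[2] - phi[1])
  ## arc in the x-z plane, centre of curvature at origin
  x <- rho_c * sin(phi); z <- rho_c * cos(phi)
  tx <- cos(phi); tz <- -sin(phi)     # local tangent
  ## incident direction at angle theta from broadside (theta = 0: normal to
  ## the chord, i.e. along -z)
  kx <- sin(theta); kz <- -cos(theta)
  ct <- kx * tx + kz * tz             # cos(angle to axis)
  cb <- sqrt(pmax(1 - ct^2, 1e-12))   # cos(beta_tilt)
  phase <- exp(2i * k2 * (kx * x + kz * z))
  integ <- sum(a * (gk - gr) * besselJ(2 * k2 * a * cb, 1) / cb * phase) * ds
  Mod((k1 / 4) * integ)^2
}

#' Target strength: DWBA uniformly bent cylinder
#'
#' Weak-scatterer (distorted-wave Born approximation) model for fluid-like
#' zooplankton such as copepods and euphausiids: a uniformly bent cylinder
#' (radius of curvature three times the body length) integrated along its
#' axis and averaged over a Gaussian orientation distribution by
#' Gauss-Legendre quadrature.
#'
#' @param spec a [scatter_spec] (`family = "dwba_bent_cylinder"` or the
#'   body part of a hybrid).
#' @param med a [medium].
#' @param f_hz acoustic frequency, Hz (vectorized).
#' @param n_quad orientation quadrature nodes (default 64).
#' @return TS in dB re 1 m2; `NA` where the cross-section is zero
#'   (null contrast).
#' @export
ts_dwba_bent_cylinder <- function(spec, med, f_hz, n_quad = 64L) {
  geo <- cylinder_geometry(spec)
  vapply(f_hz, function(f) {
    k1 <- 2 * pi * f / med$c
    mu <- spec$orient_mean_deg * pi / 180
    sd <- spec$orient_sd_deg * pi / 180
    if (sd < 1e-9) {
      sig <- dwba_sigma_at_tilt(k1, geo$a, geo$L, spec$g, spec$h, mu)
    } else {
      gl <- gauss_legendre(n_quad)
      th <- mu + 4 * sd * gl$x
      w <- gl$w * stats::dnorm(th, mu, sd)
      w <- w / sum(w)
      sig <- sum(w * vapply(th, function(t0)
        dwba_sigma_at_tilt(k1, geo$a, geo$L, spec$g, spec$h, t0), 1.0))
    }
    if (sig <= 0) NA_real_ else 10 * log10(sig)
  }, 1.0)
}

#' Target strength: randomly oriented fluid bent cylinder
#'
#' Orientation-averaged model for elongated fluid-like scatterers (shrimp,
#' salps): the bent-cylinder weak-scatterer kernel averaged uniformly over
#' all tilt angles, blended to the geometric ray limit
#' `sigma_geo = R12^2 * a * rho_c / 4` (plane-wave reflection coefficient
#' `R12 = (gh - 1)/(gh + 1)`, curvature radius `rho_c = 3L`) through the
#' high-pass form `sigma = sigma_ray / (1 + sigma_ray / sigma_geo)`, so the
#' response rises as frequency^4 in the Rayleigh regime and plateaus at
#' large `ka`.
#'
#' @inheritParams ts_dwba_bent_cylinder
#' @export
ts_fluid_bent_cylinder_random <- function(spec, med, f_hz, n_quad = 64L) {
  geo <- cylinder_geometry(spec)
  R12 <- (spec$g * spec$h - 1) / (spec$g * spec$h + 1)
  sigma_geo <- R12^2 * geo$a * (3 * geo$L) / 4
  gl <- gauss_legendre(n_quad)
  th <- (pi / 2) * gl$x               # uniform over [-90, 90] deg
  w <- gl$w / 2
  vapply(f_hz, function(f) {
    k1 <- 2 * pi * f / med$c
    s_ray <- sum(w * vapply(th, function(t0)
      dwba_sigma_at_tilt(k1, geo$a, geo$L, spec$g, spec$h, t0), 1.0))
    sig <- if (sigma_geo <= 0 || s_ray <= 0) 0 else
      s_ray / (1 + s_ray / sigma_geo)
    if (sig <= 0) NA_real_ else 10 * log10(sig)
  }, 1.0)
}

#' Target strength: high-pass dense fluid sphere
#'
#' Stanton-style high-pass sphere for dense small scatterers (gastropods):
#' `sigma_bs = a^2 (ka)^4 alpha / (1 + 4 (ka)^4 alpha / R^2)` with the
#' Rayleigh coefficient
#' `alpha = ((1 - g h^2)/(3 g h^2) + (1 - g)/(1 + 2 g))^2` and reflectivity
#' `R = (gh - 1)/(gh + 1)`; rises 40 dB/decade at small `ka` and plateaus
#' at `a^2 R^2 / 4` at large `ka`.
#'
#' @inheritParams ts_dwba_bent_cylinder
#' @export
ts_highpass_fluid_sphere <- function(spec, med, f_hz) {
  a <- if (!is.na(spec$esr_mm)) spec$esr_mm * 1e-3 else
    spec$length_mm * 1e-3 / 2
  g <- spec$g; h <- spec$h
  alpha <- ((1 - g * h^2) / (3 * g * h^2) + (1 - g) / (1 + 2 * g))^2
  R <- (g * h - 1) / (g * h + 1)
  k <- 2 * pi * f_hz / med$c
  ka <- k * a
  sig <- if (alpha == 0 || R == 0) rep(0, length(ka)) else
    a^2 * ka^4 * alpha / (1 + 4 * ka^4 * alpha / R^2)
  ifelse(sig > 0, 10 * log10(sig), NA_real_)
}

#' Minnaert resonance frequency of a gas bubble
#'
#' `f0 = 1/(2 pi a) * sqrt(3 gamma P / rho)`; surface tension ignored, gas
#' internal pressure equal to ambient.
#'
#' @param a_m bubble radius, m.
#' @param med a [medium].
#' @param gamma ratio of specific heats.
#' @return Resonance frequency, Hz.
#' @export
minnaert_frequency <- function(a_m, med, gamma = 1.4) {
  sqrt(3 * gamma * med$pressure_pa / med$rho) / (2 * pi * a_m)
}

## prolate-spheroid resonance correction via the electrostatic-capacitance
## analogy: f0 scales as sqrt(C / a_eq) for equal gas volume
prolate_resonance_factor <- function(aspect) {
  if (aspect <= 1) return(1)
  e <- sqrt(1 - 1 / aspect^2)
  A <- aspect^(2 / 3)                  # semi-major axis / a_eq
  C <- 2 * A * e / log((1 + e) / (1 - e))
  sqrt(C)
}

#' Target strength: resonant gas bubble
#'
#' Damped-resonance model
#' `sigma_bs = a^2 / (((f0/f)^2 - 1)^2 + delta^2)` with Minnaert resonance
#' and total damping `delta = ka + 4 mu / (rho omega a^2) + 3 (gamma - 1)/X`
#' (radiation, viscous, and large-argument thermal terms;
#' `X = a sqrt(2 omega / D_gas)` with the gas thermal diffusivity scaled
#' inversely with ambient pressure). The ellipsoid variant raises the
#' resonance of the equal-volume sphere by the prolate-spheroid capacitance
#' factor.
#'
#' @inheritParams ts_dwba_bent_cylinder
#' @param mu_pa_s effective viscosity, Pa s.
#' @param d_gas_atm thermal diffusivity of the gas at atmospheric pressure,
#'   m2 s-1.
#' @export
ts_gas_bubble <- function(spec, med, f_hz, mu_pa_s = 1.0e-3,
                          d_gas_atm = 2.0e-5) {
  a <- spec$esr_mm * 1e-3
  if (is.na(a) || a <= 0) stop_escore("gas bubble needs esr_mm > 0")
  f0 <- minnaert_frequency(a, med, spec$gamma)
  if (spec$family == "gas_bubble_ellipsoid" ||
      (spec$aspect > 1 && spec$family != "gas_bubble_spherical")) {
    f0 <- f0 * prolate_resonance_factor(spec$aspect)
  }
  omega <- 2 * pi * f_hz
  k <- omega / med$c
  d_gas <- d_gas_atm * (101325 / med$pressure_pa)
  X <- a * sqrt(2 * omega / d_gas)
  delta <- k * a + 4 * mu_pa_s / (med$rho * omega * a^2) +
    3 * (spec$gamma - 1) / X
  sig <- a^2 / (((f0 / f_hz)^2 - 1)^2 + delta^2)
  10 * log10(sig)
}

#' Target strength: hybrid gas inclusion + fluid body
#'
#' Incoherent cross-section sum of a resonant gas inclusion and a
#' weak-scattering fluid body (siphonophore pneumatophore + tissue; small
#' swimbladdered fish): `sigma = sigma_gas + sigma_body`.
#'
#' @inheritParams ts_dwba_bent_cylinder
#' @export
ts_hybrid <- function(spec, med, f_hz, n_quad = 64L) {
  geo <- cylinder_geometry(spec)
  esr_body <- (3 * geo$a^2 * geo$L / 4)^(1 / 3)
  gas_esr <- if (!is.na(spec$gas_esr_mm)) spec$gas_esr_mm * 1e-3 else
    0.05^(1 / 3) * esr_body           # 5 % gas volume fraction
  sig_gas <- if (gas_esr > 0) {
    gs <- spec; gs$esr_mm <- gas_esr * 1e3; gs$family <- "gas_bubble_spherical"
    db_to_linear(ts_gas_bubble(gs, med, f_hz))
  } else rep(0, length(f_hz))
  ts_body <- ts_dwba_bent_cylinder(spec, med, f_hz, n_quad)
  sig_body <- ifelse(is.na(ts_body), 0, db_to_linear(ts_body))
  sig <- sig_gas + sig_body
  ifelse(sig > 0, 10 * log10(sig), NA_real_)
}

#' Target strength of a scattering model at given frequencies
#'
#' Dispatches on the spec's family.
#' @inheritParams ts_dwba_bent_cylinder
#' @export
ts_model <- function(spec, med, f_hz) {
  switch(spec$family,
         dwba_bent_cylinder = ts_dwba_bent_cylinder(spec, med, f_hz),
         fluid_bent_cylinder_random =
           ts_fluid_bent_cylinder_random(spec, med, f_hz),
         highpass_fluid_sphere = ts_highpass_fluid_sphere(spec, med, f_hz),
         gas_bubble_spherical = ts_gas_bubble(spec, med, f_hz),
         gas_bubble_ellipsoid = ts_gas_bubble(spec, med, f_hz),
         hybrid_gas_body = ts_hybrid(spec, med, f_hz),
         stop_escore("unknown family"))
}

#' Frequency response of a scattering model
#'
#' TS at the four classification frequencies, the equivalent Sv for one
#' organism per m3 (numerically equal to TS), and the derived delta-Sv
#' triplet relative to 38 kHz.
#'
#' @param spec a [scatter_spec].
#' @param med a [medium].
#' @param freqs_khz frequencies, kHz (must include 38).
#' @return A `frequency_response`.
#' @export
frequency_response <- function(spec, med, freqs_khz = c(18, 38, 70, 120)) {
  if (!38 %in% freqs_khz) stop_escore("38 kHz reference required")
  ts <- ts_model(spec, med, freqs_khz * 1e3)
  names(ts) <- paste0(freqs_khz, "kHz")
  sv <- ts                            # Sv for 1 organism m-3
  ref <- sv[[which(freqs_khz == 38)]]
  delta <- c(d18_38 = unname(sv[[which(freqs_khz == 18)]] - ref),
             d70_38 = unname(sv[[which(freqs_khz == 70)]] - ref),
             d120_38 = unname(sv[[which(freqs_khz == 120)]] - ref))
  structure(list(spec = spec, medium = med, freqs_khz = freqs_khz,
                 ts_db = ts, sv_db = sv, delta = delta),
            class = "frequency_response")
}

#' @export
print.frequency_response <- function(x, ...) {
  cat(sprintf("<frequency_response> %s (%s)\n", x$spec$name, x$spec$family))
  cat("  TS:", paste(sprintf("%s %.1f dB", names(x$ts_db), x$ts_db),
                     collapse = ", "), "\n")
  cat(sprintf("  delta-Sv: (%.1f, %.1f, %.1f) dB\n",
              x$delta[1], x$delta[2], x$delta[3]))
  invisible(x)
}

#' Classify a scattering model into an echo-class
#'
#' Computes the model's delta-Sv triplet and scores it against a fitted
#' Escore model exactly as a one-cell grid would be scored.
#'
#' @param spec a [scatter_spec].
#' @param med a [medium].
#' @param model an `escore_model`.
#' @return List with `class` (integer, or `-1` unclassified), `escore`
#'   (winning Escore), `delta`, and `reason` when unclassifiable.
#' @export
classify_model <- function(spec, med, model) {
  fr <- frequency_response(spec, med)
  if (anyNA(fr$ts_db)) {
    return(list(class = -1L, escore = NA_real_, delta = fr$delta,
                reason = "missing TS at one or more frequencies"))
  }
  res <- classify_cells(matrix(fr$delta, 1L, 3L), model)
  list(class = res$label, escore = res$escore, delta = fr$delta,
       reason = NULL)
}

#' Read scattering-model specs from CSV
#'
#' Columns: `name,family,esr_mm_or_length_mm,g,h,lw_ratio,orient_mean_deg,
#' orient_sd_deg,aspect,gamma` -- the size column is interpreted as ESR for
#' sphere/bubble families and as body length for cylinder/hybrid families.
#'
#' @param path CSV path.
#' @return list of [scatter_spec] objects.
#' @export
read_scatter_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    fam <- df$family[i]
    size <- df$esr_mm_or_length_mm[i]
    elongated <- fam %in% c("dwba_bent_cylinder",
                            "fluid_bent_cylinder_random", "hybrid_gas_body")
    scatter_spec(df$name[i], fam,
                 esr_mm = if (elongated) NA else size,
                 length_mm = if (elongated) size else NA,
                 g = df$g[i] %||% 1.04, h = df$h[i] %||% 1.04,
                 lw_ratio = df$lw_ratio[i] %||% 4,
                 orient_mean_deg = df$orient_mean_deg[i] %||% 0,
                 orient_sd_deg = df$orient_sd_deg[i] %||% 20,
                 aspect = df$aspect[i] %||% 1,
                 gamma = df$gamma[i] %||% 1.4)
  })
}
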