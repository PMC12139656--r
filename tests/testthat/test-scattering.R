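md25 <- medium(26, 35.5, 25)

test_that("Mackenzie sound speed matches the published polynomial", {
  ## at T = 0, S = 35, D = 0 every correction term vanishes
  expect_equal(mackenzie_sound_speed(0, 35, 0), 1448.96)
  ## strictly increasing in T at S = 35, D = 0 over [0, 30]
  cs <- mackenzie_sound_speed(seq(0, 30, 0.5), 35, 0)
  expect_true(all(diff(cs) > 0))
  ## independent evaluation of the coefficient table at the calibration
  ## conditions (T = 26, S = 35.5, D = 25)
  co <- c(1448.96, 4.591, -5.304e-2, 2.374e-4, 1.340, 1.630e-2, 1.675e-7,
          -1.025e-2, -7.139e-13)
  T_ <- 26; S_ <- 35.5; D_ <- 25
  oracle <- sum(co * c(1, T_, T_^2, T_^3, S_ - 35, D_, D_^2,
                       T_ * (S_ - 35), T_ * D_^3))
  expect_equal(mackenzie_sound_speed(T_, S_, D_), oracle, tolerance = 1e-12)
  expect_warning(mackenzie_sound_speed(40, 35, 0), "envelope")
  expect_error(mackenzie_sound_speed(NA, 35, 0), "finite")
})

test_that("medium carries hydrostatic pressure", {
  m <- medium(26, 35.5, 25)
  expect_equal(m$pressure_pa, 101325 + 1025 * 9.81 * 25)
  expect_gt(m$c, 1500)
})

test_that("DWBA bent cylinder: null contrast, Rayleigh slope, small-copepod
           shape", {
  cop <- scatter_spec("copepod", "dwba_bent_cylinder", length_mm = 2,
                      g = 1.04, h = 1.04, lw_ratio = 3, orient_sd_deg = 20)
  ## g = h = 1 -> zero contrast -> MISSING TS
  null <- scatter_spec("null", "dwba_bent_cylinder", length_mm = 2,
                       g = 1, h = 1)
  expect_true(all(is.na(ts_dwba_bent_cylinder(null, md25,
                                              c(18, 38, 70) * 1e3))))
  ## Rayleigh regime: 40 log10(f2/f1) +/- 2 dB
  t1 <- ts_dwba_bent_cylinder(cop, md25, 4e3)
  t2 <- ts_dwba_bent_cylinder(cop, md25, 8e3)
  expect_lt(abs((t2 - t1) - 40 * log10(2)), 2)
  ## small copepod: rising response toward 38 kHz -> dSv18-38 < 0
  fr <- frequency_response(cop, md25)
  expect_lt(fr$delta[["d18_38"]], 0)
})

test_that("randomly oriented fluid bent cylinder has fluid-model limits", {
  sh <- scatter_spec("shrimp", "fluid_bent_cylinder_random", length_mm = 8,
                     g = 1.04, h = 1.04, lw_ratio = 5)
  ## null contrast -> null return
  null <- scatter_spec("null", "fluid_bent_cylinder_random", length_mm = 8,
                       g = 1, h = 1)
  expect_true(all(is.na(ts_fluid_bent_cylinder_random(null, md25, 38e3))))
  ## geometric regime: TS increases over a doubling of length
  long <- scatter_spec("shrimp2", "fluid_bent_cylinder_random",
                       length_mm = 16, g = 1.04, h = 1.04, lw_ratio = 5)
  expect_gt(ts_fluid_bent_cylinder_random(long, md25, 200e3),
            ts_fluid_bent_cylinder_random(sh, md25, 200e3))
  ## Rayleigh agreement with the DWBA kernel for weak contrast, small ka
  small <- scatter_spec("tiny", "fluid_bent_cylinder_random", length_mm = 1,
                        g = 1.02, h = 1.02, lw_ratio = 3)
  small_dwba <- scatter_spec("tiny", "dwba_bent_cylinder", length_mm = 1,
                             g = 1.02, h = 1.02, lw_ratio = 3,
                             orient_sd_deg = 30)
  expect_lt(abs(ts_fluid_bent_cylinder_random(small, md25, 5e3) -
                ts_dwba_bent_cylinder(small_dwba, md25, 5e3)), 3)
})

test_that("high-pass fluid sphere: Rayleigh slope, plateau, a^6 scaling", {
  gast <- scatter_spec("gastropod", "highpass_fluid_sphere", esr_mm = 1,
                       g = 1.43, h = 1.3)
  ## 40 dB/decade at small ka
  expect_lt(abs((ts_highpass_fluid_sphere(gast, md25, 20e3) -
                 ts_highpass_fluid_sphere(gast, md25, 2e3)) - 40), 2)
  ## plateau at large ka: 70 vs 120 kHz within 1 dB
  big <- scatter_spec("big", "highpass_fluid_sphere", esr_mm = 40,
                      g = 1.43, h = 1.3)
  expect_lt(abs(ts_highpass_fluid_sphere(big, md25, 120e3) -
                ts_highpass_fluid_sphere(big, md25, 70e3)), 1)
  ## Rayleigh a -> 2a raises TS by 10 log10(2^6)
  g2 <- scatter_spec("g2", "highpass_fluid_sphere", esr_mm = 2,
                     g = 1.43, h = 1.3)
  expect_equal(ts_highpass_fluid_sphere(g2, md25, 1e3) -
               ts_highpass_fluid_sphere(gast, md25, 1e3),
               10 * log10(2^6), tolerance = 0.1)
  ## null contrast
  null <- scatter_spec("null", "highpass_fluid_sphere", esr_mm = 1,
                       g = 1, h = 1)
  expect_true(all(is.na(ts_highpass_fluid_sphere(null, md25, 38e3))))
})

test_that("gas bubble resonance follows Minnaert and the geometric limit", {
  sp <- scatter_spec("bubble", "gas_bubble_spherical", esr_mm = 0.16)
  f <- seq(5e3, 150e3, by = 100)
  ts <- ts_gas_bubble(sp, md25, f)
  fpeak <- f[which.max(ts)]
  f0 <- minnaert_frequency(0.16e-3, md25)
  expect_lt(abs(fpeak - f0) / f0, 0.10)
  expect_true(fpeak > 30e3 && fpeak < 45e3)
  ## f0 decreases as a increases (f0 ~ 1/a)
  expect_lt(minnaert_frequency(0.32e-3, md25), f0)
  expect_equal(minnaert_frequency(0.32e-3, md25), f0 / 2, tolerance = 1e-12)
  ## f >> f0: sigma -> a^2 / (1 + delta^2) (the (f0/f)^2 term vanishes)
  fh <- 50 * f0
  a <- 0.16e-3
  kh <- 2 * pi * fh / md25$c
  delta_h <- kh * a + 4 * 1e-3 / (md25$rho * 2 * pi * fh * a^2) +
    3 * 0.4 / (a * sqrt(2 * 2 * pi * fh /
                        (2e-5 * 101325 / md25$pressure_pa)))
  expect_equal(ts_gas_bubble(sp, md25, fh),
               10 * log10(a^2 / (1 + delta_h^2)), tolerance = 1e-3)
  ## ellipsoid variant raises the resonance of the equal-volume sphere
  el <- scatter_spec("eb", "gas_bubble_ellipsoid", esr_mm = 0.16, aspect = 4)
  tse <- ts_gas_bubble(el, md25, f)
  expect_gt(f[which.max(tse)], fpeak)
  expect_error(ts_gas_bubble(scatter_spec("x", "gas_bubble_spherical",
                                          esr_mm = 1e-9) |>
                               (\(s) { s$esr_mm <- -1; s })(), md25, 38e3),
               "esr_mm")
})

test_that("hybrid model sums cross-sections incoherently", {
  fish <- scatter_spec("fish", "hybrid_gas_body", length_mm = 65,
                       g = 1.04, h = 1.04, lw_ratio = 5, orient_sd_deg = 15)
  f4 <- c(18, 38, 70, 120) * 1e3
  ts_h <- ts_hybrid(fish, md25, f4)
  ## hybrid >= each component everywhere
  gs <- fish; gs$family <- "gas_bubble_spherical"
  geo <- escore:::cylinder_geometry(fish)
  gs$esr_mm <- 0.05^(1 / 3) * (3 * geo$a^2 * geo$L / 4)^(1 / 3) * 1e3
  ts_g <- ts_gas_bubble(gs, md25, f4)
  ts_b <- ts_dwba_bent_cylinder(fish, md25, f4)
  expect_true(all(ts_h >= ts_g - 1e-9))
  expect_true(all(ts_h >= ts_b - 1e-9, na.rm = TRUE))
  ## at the gas resonance the bubble dominates: hybrid within 1 dB of gas
  f0 <- minnaert_frequency(gs$esr_mm * 1e-3, md25)
  expect_lt(abs(ts_hybrid(fish, md25, f0) - ts_gas_bubble(gs, md25, f0)), 1)
  ## gas fraction -> 0 reduces to the body alone
  nogas <- fish; nogas$gas_esr_mm <- 0
  expect_equal(ts_hybrid(nogas, md25, f4), ts_b, tolerance = 1e-9)
})

test_that("scattering models classify exactly like a one-cell grid", {
  m <- random_model(6)
  fish <- scatter_spec("fish", "hybrid_gas_body", length_mm = 65,
                       g = 1.04, h = 1.04, lw_ratio = 5)
  res <- classify_model(fish, md25, m)
  fr <- frequency_response(fish, md25)
  direct <- classify_cells(matrix(fr$delta, 1, 3), m)
  expect_equal(res$class, direct$label)
  expect_equal(res$escore, direct$escore)

  ## a spec whose delta equals a class centroid lands there with Escore 0
  ## (constructed via a synthetic frequency response)
  x <- matrix(m$mu[2, ], 1, 3)
  expect_equal(classify_cells(x, m)$label, 2L)
  expect_equal(classify_cells(x, m)$escore, 0)

  ## >= 3 sigma off every centroid on every axis -> unclassified (27 >= 25)
  far <- m$mu[1, ] + 3.001 * m$sigma[1, ]
  scores <- vapply(1:m$k, function(g) escore(far, g, m), 1.0)
  if (all(scores >= 25)) {
    expect_equal(classify_cells(matrix(far, 1, 3), m)$label, -1L)
  }

  ## null-contrast model -> unclassified with a reason
  null <- scatter_spec("null", "dwba_bent_cylinder", length_mm = 2,
                       g = 1, h = 1)
  resn <- classify_model(null, md25, m)
  expect_equal(resn$class, -1L)
  expect_match(resn$reason, "missing TS")
})

test_that("a synthetic 18-kHz-dominant class captures the hybrid fish", {
  ## library built so one class is 18-kHz dominant (positive d18_38,
  ## falling response), as large gas-bearing scatterers are
  md <- md25
  fish <- scatter_spec("fish", "hybrid_gas_body", length_mm = 65,
                       g = 1.04, h = 1.04, lw_ratio = 5)
  fr <- frequency_response(fish, md)
  cent <- rbind(c(-7, -1, -2), fr$delta + c(0.5, -0.3, 0.2),
                c(-14, -9, -13))
  lib <- planted_library(cent, n_per_class = 20, sd = 1, seed = 7)
  lib <- hierarchical_classify(lib, 3)
  m <- fit_ellipsoids(lib)
  res <- classify_model(fish, md, m)
  ## the class nearest the planted fish-like centroid wins
  dists <- rowSums(sweep(m$mu, 2, fr$delta)^2)
  expect_equal(res$class, unname(which.min(dists)))
  expect_lt(res$escore, 25)
})

test_that("scatter spec CSV reader dispatches size by family", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "name,family,esr_mm_or_length_mm,g,h,lw_ratio,orient_mean_deg,orient_sd_deg,aspect,gamma",
    "cop,dwba_bent_cylinder,2,1.04,1.04,3,0,20,1,1.4",
    "bub,gas_bubble_spherical,0.16,1,1,1,0,0,1,1.4"), p)
  specs <- read_scatter_csv(p)
  expect_equal(specs[[1]]$length_mm, 2)
  expect_true(is.na(specs[[1]]$esr_mm))
  expect_equal(specs[[2]]$esr_mm, 0.16)
  expect_error(scatter_spec("x", "nope", esr_mm = 1), "family")
  expect_error(scatter_spec("x", "dwba_bent_cylinder"), "esr_mm or length")
})
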