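test_that("Sv CSV round-trips: identity, missing cells, byte-exact rewrite", {
  eg <- tiny_echogram(matrix(-70, 2, 3))
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_sv_csv(eg, p1)
  back <- read_sv_csv(p1, 38)
  expect_equal(back$sv, eg$sv)
  expect_equal(back$depth_edges, eg$depth_edges)
  expect_equal(as.numeric(back$ping_times), as.numeric(eg$ping_times))

  ## one empty cell -> MISSING, others intact
  sv <- matrix(-70, 2, 3); sv[1, 2] <- NA
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_sv_csv(tiny_echogram(sv), p2)
  back2 <- read_sv_csv(p2, 38)
  expect_true(is.na(back2$sv[1, 2]))
  expect_equal(back2$sv[!is.na(sv)], sv[!is.na(sv)])

  ## write -> read -> write is byte-identical on random grids
  for (seed in 1:3) {
    eg_r <- random_echogram(7, 11, seed = seed)
    a <- withr::local_tempfile(fileext = ".csv")
    b <- withr::local_tempfile(fileext = ".csv")
    write_sv_csv(eg_r, a)
    write_sv_csv(read_sv_csv(a, 38), b)
    expect_identical(readLines(a), readLines(b))
  }
})

test_that("malformed Sv CSV inputs are rejected", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,x,y,d_15.0_16.5", "2022-04-26T00:00:00.000Z,,,-70"), p)
  expect_error(read_sv_csv(p, 38), "header")
  writeLines(c("ping_time,lat,lon,d_16.5_15.0",
               "2022-04-26T00:00:00.000Z,,,-70"), p)
  expect_error(read_sv_csv(p, 38), "depth|monotone")
})

test_that("echogram construction enforces lattice invariants", {
  expect_error(tiny_echogram(matrix(Inf, 1, 1)), "finite")
  expect_error(echogram(matrix(-70, 2, 2),
                        as.POSIXct(c("2022-01-01 00:00:03",
                                     "2022-01-01 00:00:00"), tz = "UTC"),
                        c(15, 16.5, 18), 38), "non-decreasing")
  expect_error(echogram(matrix(-70, 1, 2),
                        as.POSIXct("2022-01-01", tz = "UTC"),
                        c(15, 18, 16.5), 38), "increasing")
})

test_that("echo-integration matches the linear-domain definition", {
  cfg <- integration_config(surface_exclusion_m = 0,
                            max_depth_m = numeric(0))
  ## constant input: 3 pings x one bin of -70 -> -70
  eg <- tiny_echogram(matrix(-70, 3, 1), edge0 = 0)
  out <- echo_integrate(eg, cfg)
  expect_equal(out$sv[1, 1], -70)

  ## two samples -70 and -80 -> 10*log10((1e-7 + 1e-8)/2)
  eg2 <- tiny_echogram(matrix(c(-70, -80), 2, 1), edge0 = 0)
  out2 <- echo_integrate(eg2, integration_config(
    esdu_pings = 2, surface_exclusion_m = 0, max_depth_m = numeric(0)))
  expect_equal(out2$sv[1, 1], 10 * log10((1e-7 + 1e-8) / 2), tolerance = 1e-12)

  ## all samples below -100 dB -> zero linear sum -> MISSING
  eg3 <- tiny_echogram(matrix(-120, 3, 1), edge0 = 0)
  expect_true(is.na(echo_integrate(eg3, cfg)$sv[1, 1]))

  ## all samples MISSING -> MISSING
  eg4 <- tiny_echogram(matrix(NA_real_, 3, 1), edge0 = 0)
  expect_true(is.na(echo_integrate(eg4, cfg)$sv[1, 1]))
})

test_that("echo-integration equals a brute-force oracle on random grids", {
  set.seed(42)
  for (rep in 1:5) {
    n_p <- 9; n_b <- 8
    sv <- matrix(stats::rnorm(n_p * n_b, -85, 12), n_p, n_b)
    sv[sample(length(sv), 6)] <- NA
    ## raw at 0.5 m so 3 raw bins = one 1.5 m ESDU bin
    raw <- echogram(sv, as.POSIXct("2022-01-01", tz = "UTC") + (1:n_p),
                    0.5 * (0:n_b), 38)
    out <- echo_integrate(raw, integration_config(
      surface_exclusion_m = 0, max_depth_m = numeric(0)))
    ## oracle: plain mean over the 3x3 sample block in the linear domain
    for (gi in seq_len(nrow(out$sv))) {
      for (bj in seq_len(ncol(out$sv))) {
        rows <- ((gi - 1) * 3 + 1):min(gi * 3, n_p)
        cols <- ((bj - 1) * 3 + 1):min(bj * 3, n_b)
        s <- sv[rows, cols]
        lin <- ifelse(is.na(s), NA, ifelse(s < -100, 0, 10^(s / 10)))
        m <- mean(lin, na.rm = TRUE)
        expected <- if (all(is.na(lin)) || m <= 0) NA_real_ else 10 * log10(m)
        if (is.na(expected)) {
          expect_true(is.na(out$sv[gi, bj]))
        } else {
          expect_equal(out$sv[gi, bj], expected, tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("raising a constituent sample never lowers the ESDU cell", {
  set.seed(7)
  sv <- matrix(stats::rnorm(9, -80, 5), 3, 3)
  raw <- echogram(sv, as.POSIXct("2022-01-01", tz = "UTC") + (1:3),
                  0.5 * (0:3), 38)
  cfg <- integration_config(surface_exclusion_m = 0,
                            max_depth_m = numeric(0))
  base <- echo_integrate(raw, cfg)$sv[1, 1]
  for (i in 1:3) for (j in 1:3) {
    sv2 <- sv; sv2[i, j] <- sv2[i, j] + 5
    raw2 <- echogram(sv2, raw$ping_times, raw$depth_edges, 38)
    expect_gte(echo_integrate(raw2, cfg)$sv[1, 1], base)
  }
})

test_that("surface exclusion and per-frequency max depth trim bins", {
  sv <- matrix(-70, 3, 200)
  raw <- echogram(sv, as.POSIXct("2022-01-01", tz = "UTC") + (1:3),
                  1.5 * (0:200), 120)
  out <- echo_integrate(raw, integration_config())
  expect_gte(min(out$depth_edges), 15)       # top 15 m removed
  expect_lte(max(out$depth_edges), 250)      # 120 kHz limited to 250 m
})

test_that("NASC matches the closed form and is additive and linear", {
  ## one 1.5 m bin at -70: sA = 4*pi*1852^2 * 1e-7 * 1.5
  eg <- tiny_echogram(matrix(-70, 1, 1), edge0 = 20)
  expect_equal(sv_to_nasc(eg, 20, 21.5),
               4 * pi * 1852^2 * 1e-7 * 1.5, tolerance = 1e-12)

  ## all-missing -> 0
  egm <- tiny_echogram(matrix(NA_real_, 2, 3))
  expect_equal(sv_to_nasc(egm, 15, 19.5), c(0, 0))

  ## additivity over disjoint depth intervals (exact in linear domain)
  egr <- random_echogram(5, 12, seed = 3)
  lo <- min(egr$depth_edges); hi <- max(egr$depth_edges)
  mid <- egr$depth_edges[7]
  expect_equal(sv_to_nasc(egr, lo, mid) + sv_to_nasc(egr, mid, hi + 1e-9),
               sv_to_nasc(egr, lo, hi + 1e-9))

  ## doubling linear sv doubles sA
  eg2 <- egr; eg2$sv <- egr$sv + 10 * log10(2)
  expect_equal(sv_to_nasc(eg2, lo, hi + 1e-9),
               2 * sv_to_nasc(egr, lo, hi + 1e-9))

  expect_error(sv_to_nasc(egr, 10, 10), "depth_from")
})

test_that("frequency alignment preserves per-frequency limits", {
  ## identical lattices in, identical set out
  set1 <- constant_set()
  expect_equal(set1$sv[["18"]], set1$sv[["38"]] - 5)

  ## 120 kHz limited to 250 m: joint 4-frequency cells only above 250 m
  n <- 3
  mk <- function(f, nb) tiny_echogram(matrix(-75, n, nb), freq = f,
                                      edge0 = 15)
  egs <- list(mk(18, 300), mk(38, 300), mk(70, 300), mk(120, 156))
  set <- align_frequencies(egs)
  grid <- compute_delta_sv(set)
  tops <- set$depth_edges[-length(set$depth_edges)]
  expect_true(all(is.na(grid$d18_38[, tops >= 15 + 1.5 * 156])))
  expect_true(all(!is.na(grid$d18_38[, tops < 15 + 1.5 * 156])))

  ## randomized depth ranges vs brute-force intersection oracle
  set.seed(5)
  for (rep in 1:4) {
    nbs <- sample(5:30, 4)
    egs <- Map(mk, c(18, 38, 70, 120), nbs)
    set <- align_frequencies(egs)
    joint <- !is.na(compute_delta_sv(set)$d18_38[1, ])
    expect_equal(sum(joint), min(nbs))
  }

  ## ping-time mismatch -> alignment error
  bad <- tiny_echogram(matrix(-75, n, 10), freq = 120, t0 = "2022-04-26 07:00:00")
  expect_error(align_frequencies(list(mk(38, 10), bad)), "mismatch")
})

test_that("solar classification: noon day, midnight night, twilight bands", {
  equinox_noon <- as.POSIXct("2023-03-20 12:00:00", tz = "UTC")
  expect_equal(as.character(classify_solar(equinox_noon, 0, 0)), "day")
  expect_equal(as.character(classify_solar(equinox_noon - 12 * 3600, 0, 0)),
               "night")
  ## scan a sunrise: below -6 night, inside band ascending sunrise, then day
  times <- as.POSIXct("2023-03-20 00:00:00", tz = "UTC") + seq(0, 86100, 300)
  p <- classify_solar(times, 0, 0)
  el <- solar_elevation(times, 0, 0)
  expect_true(all(as.character(p[el > 6]) == "day"))
  expect_true(all(as.character(p[el < -6]) == "night"))
  band <- abs(el) <= 6
  expect_setequal(unique(as.character(p[band])), c("sunrise", "sunset"))
  ## symmetric about solar noon: one sunrise run before, one sunset run after
  expect_equal(sum(rle(as.character(p))$values == "sunrise"), 1)
  expect_equal(sum(rle(as.character(p))$values == "sunset"), 1)
  expect_error(classify_solar(equinox_noon, 95, 0), "latitude")
})
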