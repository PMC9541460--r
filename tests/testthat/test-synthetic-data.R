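test_that("grid generation is deterministic, bounded and masked", {
  g1 <- generate_grid(resolution = 2, seed = 1)
  g2 <- generate_grid(resolution = 2, seed = 1)
  expect_identical(g1, g2)
  expect_true(all(g1$cells$depth >= 4 & g1$cells$depth <= 50))
  expect_gte(n_cells(g1), 25L)
  g3 <- generate_grid(resolution = 2, seed = 2)
  expect_false(identical(g1$depth, g3$depth))
})

test_that("degenerate grid configurations error", {
  expect_error(generate_grid(resolution = 8, seed = 1), "25 valid cells")
  expect_error(generate_grid(lon_min = 150, lon_max = 140), "well-ordered")
  expect_error(generate_grid(resolution = -1), "positive")
})

test_that("mixing contrast plants coherent high-tide patches", {
  g <- small_grid()
  f0 <- generate_forcing(g, years = 2000, mixing_contrast = 0, seed = 7)
  gap0 <- mean(f0$u0[f0$high_mix]) - mean(f0$u0[!f0$high_mix])
  expect_lt(abs(gap0), 0.06)        # homogeneous up to smooth background
  f <- generate_forcing(g, years = 2000, mixing_contrast = 0.5, seed = 7)
  expect_gt(mean(f$u0[f$high_mix]), mean(f$u0[!f$high_mix]) + 0.3)
  expect_true(all(f$u0 >= 0) && all(f$wind_speed >= 0) &&
                all(f$shortwave >= 0))
  expect_error(generate_forcing(g, years = 2000, mixing_contrast = -0.1),
               "non-negative")
})

test_that("wind dipole strengthens northern and weakens southern future winds", {
  g <- small_grid()
  f <- generate_forcing(g, years = c(2000:2004, 2090:2094), dipole = TRUE,
                        seed = 2)
  yr <- as.integer(format(f$dates, "%Y"))
  present <- colMeans(f$wind_speed[yr <= 2004, ])
  future <- colMeans(f$wind_speed[yr >= 2090, ])
  north <- g$cells$lat > mean(range(g$cells$lat))
  change <- future - present
  expect_gt(mean(change[north]), 0)
  expect_lt(mean(change[!north]), 0)
})

test_that("noise-free, trend-free SST is an exact 365.25-day harmonic", {
  g <- small_grid()
  f <- generate_forcing(g, years = 2000:2007, seed = 1)
  s <- scenario_spec("SSP1-1.9", warming_2100 = 0, noise_sd = 0,
                     heatwave_rate = 0, years = 2000:2007, seed = 1)
  x <- generate_daily_sst(g, f, s)
  # 4 years = 1461 days = 4 * 365.25: the harmonic must repeat exactly
  n <- length(x$dates)
  expect_equal(x$sst[1:(n - 1461), ], x$sst[1462:n, ], tolerance = 1e-12)
})

test_that("SST generation is deterministic and validates its inputs", {
  g <- small_grid()
  f <- generate_forcing(g, years = 2000:2001, seed = 1)
  s <- scenario_spec("SSP3-7.0", years = 2000:2001, seed = 5)
  expect_identical(generate_daily_sst(g, f, s)$sst,
                   generate_daily_sst(g, f, s)$sst)
  s_long <- scenario_spec("SSP3-7.0", years = 1999:2001, seed = 5)
  expect_error(generate_daily_sst(g, f, s_long), "calendar mismatch")
  g2 <- generate_grid(resolution = 2, seed = 99)
  expect_error(generate_daily_sst(g2, f, s), "different cells")
})

test_that("strong tidal mixing damps summer SST extremes", {
  g <- small_grid()
  f <- generate_forcing(g, years = 2000:2009, mixing_contrast = 0, seed = 3)
  # two cells identical in forcing except their tidal amplitude
  f$u0[] <- 0
  f$u0[2] <- 1
  f$wind_mean_cell[] <- mean(f$wind_mean_cell)
  s <- scenario_spec("SSP1-1.9", warming_2100 = 0, years = 2000:2009,
                     seed = 3)
  x <- generate_daily_sst(g, f, s)
  doy <- format(x$dates, "%m-%d")
  anom1 <- x$sst[, 1] - ave(x$sst[, 1], doy)
  anom2 <- x$sst[, 2] - ave(x$sst[, 2], doy)
  summer <- as.integer(format(x$dates, "%m")) %in% c(12L, 1L, 2L)
  expect_lt(quantile(anom2[summer], 0.99), quantile(anom1[summer], 0.99))
})

test_that("planted linear trend is recovered from decadal SST means", {
  g <- small_grid()
  f <- generate_forcing(g, years = 1950:2100, mixing_contrast = 0.5,
                        seed = 4)
  s <- scenario_spec("SSP5-8.5", warming_2100 = 4, trend_shape = "linear",
                     damping_max = 0, years = 1950:2100, seed = 4)
  x <- generate_daily_sst(g, f, s)
  yr <- as.integer(format(x$dates, "%Y"))
  late <- yr >= 2091
  early <- yr <= 1959
  measured <- mean(x$sst[late, ]) - mean(x$sst[early, ])
  planted <- s$local_warming_ratio *
    (mean(warming_path(s, decimal_year(x$dates[late]))) -
       mean(warming_path(s, decimal_year(x$dates[early]))))
  expect_equal(measured, planted, tolerance = 0.1)
})

test_that("global tas trajectories honour their anchors", {
  s0 <- scenario_spec("SSP1-1.9", warming_2100 = 0, seed = 1)
  flat <- generate_global_tas(s0, noise_sd = 0)
  expect_equal(max(abs(warming_anomaly(flat)$anomaly)), 0, tolerance = 1e-12)
  s3 <- scenario_spec("SSP3-7.0", warming_2100 = 3, seed = 1)
  an <- warming_anomaly(generate_global_tas(s3, noise_sd = 0))
  expect_equal(an$anomaly[an$year == 2100], 3, tolerance = 1e-10)
  expect_identical(generate_global_tas(s3), generate_global_tas(s3))
})

test_that("scenario defaults order warming across pathways", {
  w <- vapply(c("SSP1-1.9", "SSP1-2.6", "SSP3-7.0", "SSP5-8.5"),
              function(s) scenario_spec(s)$warming_2100, numeric(1))
  expect_true(all(diff(w) >= 0))
  expect_lt(w["SSP1-1.9"], 1.5)
  expect_lt(w["SSP1-2.6"], 2.0)
})

test_that("ensemble generation counts members and perturbs models", {
  g <- small_grid()
  f <- generate_forcing(g, years = 2000:2001, seed = 1)
  ens <- generate_ensemble(g, f, scenarios = c("SSP1-1.9", "SSP5-8.5"),
                           n_models = 2, years = 2000:2001, seed = 1)
  expect_length(ens, 4L)
  expect_error(
    generate_ensemble(g, f, n_models = 2, model_ids = c("A", "A"),
                      years = 2000:2001),
    "duplicate"
  )
  ens0 <- generate_ensemble(g, f, scenarios = "SSP5-8.5", n_models = 2,
                            perturbation = 0, years = 2000:2001, seed = 1)
  expect_identical(ens0[[1]]$sst$sst, ens0[[2]]$sst$sst)
  anom2100 <- vapply(ens[c("SSP5-8.5/M1", "SSP5-8.5/M2")], function(m) {
    a <- warming_anomaly(m$tas)
    a$anomaly[a$year == 2100]
  }, numeric(1))
  expect_gt(diff(range(anom2100)), 0)
})
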