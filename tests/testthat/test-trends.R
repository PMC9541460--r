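test_that("the DHW difference contrasts the two groups per year", {
  am <- make_annual_max(matrix(c(2, 2, 5, 5, 5), 3, 5, byrow = TRUE),
                        2000:2002)
  mask <- make_mask(c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(dhw_difference(am, mask)$diff, rep(3, 3))
  same <- make_annual_max(matrix(4, 2, 5), 2000:2001)
  expect_equal(dhw_difference(same, mask)$diff, c(0, 0))
  set.seed(14)
  m <- matrix(runif(3 * 5, 0, 10), 3, 5)
  amr <- make_annual_max(m, 2000:2002)
  oracle <- apply(m, 1, function(v) {
    median(v[!mask$is_refugium]) - median(v[mask$is_refugium])
  })
  expect_equal(dhw_difference(amr, mask)$diff, unname(oracle))
  expect_equal(
    dhw_difference(amr, mask, aggregate = "mean")$diff,
    unname(apply(m, 1, function(v) {
      mean(v[!mask$is_refugium]) - mean(v[mask$is_refugium])
    }))
  )
  expect_error(dhw_difference(amr, make_mask(rep(TRUE, 5))), "non-empty")
})

test_that("rolling mean is centred and flags incomplete ends", {
  expect_equal(rolling_mean(rep(4, 20), 11), c(rep(NA, 5), rep(4, 10),
                                               rep(NA, 5)))
  lin <- rolling_mean(1:21, 11)
  expect_equal(lin[6:16], 6:16)                 # linear interior unchanged
  set.seed(6)
  x <- rnorm(40)
  got <- rolling_mean(x, 7)
  oracle <- vapply(1:40, function(i) {
    if (i < 4 || i > 37) NA_real_ else mean(x[(i - 3):(i + 3)])
  }, numeric(1))
  expect_equal(got, oracle)
  expect_equal(rolling_mean(x, 7) + 2, rolling_mean(x + 2, 7))
  expect_error(rolling_mean(x, 6), "odd")
  expect_error(rolling_mean(1:5, 7), "longer")
})

test_that("warming anomalies are measured against 1860-1880", {
  tas <- structure(data.frame(year = 1860:2100, tas = 14),
                   class = c("global_tas", "data.frame"))
  expect_equal(warming_anomaly(tas)$anomaly, rep(0, 241))
  tas$tas[tas$year == 2100] <- 17
  an <- warming_anomaly(tas)
  expect_equal(an$anomaly[an$year == 2100], 3)
  short <- tas[tas$year >= 1870, ]
  expect_error(warming_anomaly(short), "baseline")
})

test_that("the quadratic fit recovers a noiseless linear failure law", {
  w <- seq(0.5, 4, by = 0.05)
  pairs <- data.frame(warming = w, diff = 1.5 - 0.5 * w)
  fit <- suppressWarnings(fit_diff_vs_warming(pairs))
  expect_lt(abs(fit$coefficients["a2"]), 1e-8)
  expect_equal(fit$crossing, 3, tolerance = 1e-6)
  pred <- predict(fit, c(1, 3))
  expect_equal(pred$fit, c(1, 0), tolerance = 1e-8)

  flat <- data.frame(warming = w, diff = 2 + 0.01 * w)
  expect_true(is.na(suppressWarnings(fit_diff_vs_warming(flat))$crossing))
  expect_error(fit_diff_vs_warming(pairs[1:4, ]), "at least 6")
  degenerate <- data.frame(warming = rep(1, 10), diff = rnorm(10))
  expect_error(fit_diff_vs_warming(degenerate), "rank-deficient")
})

test_that("an ascending zero at the foot of the range is not a crossing", {
  # rises through zero early, falls through zero late: the refugia-loss
  # point is the descending root
  w <- seq(0.2, 4, by = 0.05)
  pairs <- data.frame(warming = w, diff = -(w - 0.5) * (w - 3))
  fit <- suppressWarnings(fit_diff_vs_warming(pairs))
  expect_equal(fit$crossing, 3, tolerance = 1e-6)
})

test_that("relative warming slopes regress cell anomalies on year", {
  years <- 2014:2040
  ny <- length(years)
  base <- matrix(5 + 0.1 * (years - 2014), ny, 4)   # non-refugia cells
  track <- base[, 1]                                # refugium tracking baseline
  drift <- base[, 1] + 0.1 * (years - 2014)         # refugium drifting +0.1/yr
  am <- make_annual_max(cbind(track, drift, base), years)
  mask <- make_mask(c(TRUE, TRUE, rep(FALSE, 4)))
  sl <- relative_warming_slope(am, mask, period = years)
  expect_equal(sl$slope, c(0, 0.1), tolerance = 1e-10)
  expect_equal(sl$cell, 1:2)

  set.seed(21)
  m <- matrix(rnorm(ny * 6, 5), ny, 6)
  am2 <- make_annual_max(m, years)
  mask2 <- make_mask(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  sl2 <- relative_warming_slope(am2, mask2, period = years)
  basemed <- apply(m[, 4:6], 1, median)
  oracle <- vapply(1:3, function(j) {
    unname(coef(lm((m[, j] - basemed) ~ years))[2])
  }, numeric(1))
  expect_equal(sl2$slope, oracle, tolerance = 1e-10)
  # whole-grid baseline variant
  sl3 <- relative_warming_slope(am2, mask2, baseline = "grid",
                                period = years)
  gridmed <- apply(m, 1, median)
  oracle3 <- vapply(1:3, function(j) {
    unname(coef(lm((m[, j] - gridmed) ~ years))[2])
  }, numeric(1))
  expect_equal(sl3$slope, oracle3, tolerance = 1e-10)
  expect_error(relative_warming_slope(am2, mask2, period = 2014:2100),
               "missing")
})

test_that("bleaching years and atmospheric change respect their windows", {
  gm <- setNames(c(1.9, 2.0, 3.5), 2001:2003)
  expect_equal(detect_bleaching_years(gm), c(2002L, 2003L))

  dates <- daily_dates(c(1999:2002, 2050:2053))
  n <- length(dates)
  yr <- as.integer(format(dates, "%Y"))
  field <- matrix(10, n, 3)
  field[yr >= 2050, ] <- 11                        # future 1.1 x present
  pct <- atmos_change(field, dates, bleaching_years = c(2000:2002, 2051:2053),
                      present = 1999:2019, future = 2050:2100)
  expect_equal(pct, rep(10, 3), tolerance = 1e-10)
  expect_error(
    atmos_change(field, dates, bleaching_years = 2051:2053,
                 present = 1999:2019, future = 2050:2100),
    "present"
  )
})

test_that("the planted wind dipole shows up in the future change map", {
  g <- generate_grid(resolution = 2, seed = 5)
  f <- generate_forcing(g, years = c(1999:2003, 2050:2060), dipole = TRUE,
                        seed = 5)
  pct <- atmos_change(f$wind_speed, f$dates,
                      bleaching_years = c(2000:2003, 2051:2060),
                      present = 1999:2019, future = 2050:2100)
  north <- g$cells$lat > mean(range(g$cells$lat))
  expect_gt(mean(pct[north]), 0)
  expect_lt(mean(pct[!north]), 0)
})
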