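test_that("hotspot is the positive part of SST minus MMM", {
  dates <- daily_dates(2000)
  n <- length(dates)
  set.seed(1)
  sstmat <- matrix(27 + rnorm(n * 3, sd = 2), n, 3)
  x <- make_sst(sstmat, dates)
  mmm <- structure(list(climatology = matrix(28, 12, 3), mmm = rep(28, 3),
                        centre_year = 1988.2857), class = "mmm_field")
  hs <- hotspot(x, mmm)
  expect_equal(hs$hotspot, pmax(sstmat - 28, 0))  # elementwise oracle
  expect_true(all(hs$hotspot >= 0))
  mmm2 <- mmm; mmm2$mmm <- rep(28, 2); mmm2$climatology <- matrix(28, 12, 2)
  expect_error(hotspot(x, mmm2), "mismatch")
})

test_that("dhw accumulates qualifying hotspots over 84 days", {
  dates <- daily_dates(2000)
  n <- length(dates)
  # 2 degC sustained for exactly the first 84 days
  hs <- make_hotspot(cbind(c(rep(2, 84), rep(0, n - 84)),
                           rep(0, n),
                           rep(0.5, n)), dates)
  d <- dhw(hs)
  expect_true(all(is.na(d$dhw[1:83, ])))
  expect_equal(d$dhw[84, 1], 84 * 2 / 7)           # = 24 degC-weeks
  expect_equal(d$dhw[84, 2], 0)
  expect_true(all(d$dhw[84:n, 3] == 0))            # 0.5 below the 1 degC floor
  expect_true(all(d$dhw[84:n, ] >= 0))
  # in exact-text mode (no weekly conversion) the same window gives 168
  expect_equal(dhw(hs, weekly_divisor = 1)$dhw[84, 1], 168)
})

test_that("dhw matches the naive window oracle on random series", {
  set.seed(11)
  dates <- daily_dates(2000)
  n <- length(dates)
  for (k in 1:10) {
    v <- pmax(rnorm(n, 0.5, 1), 0)
    got <- dhw(make_hotspot(matrix(v, n, 1), dates))$dhw[, 1]
    expect_equal(got, naive_dhw(v), tolerance = 1e-10)
  }
})

test_that("dhw is monotone in SST and bounded by the window maximum", {
  set.seed(3)
  dates <- daily_dates(2000)
  n <- length(dates)
  v <- pmax(rnorm(n, 0.8, 1), 0)
  base <- dhw(make_hotspot(matrix(v, n, 1), dates))$dhw[, 1]
  v2 <- v
  v2[200] <- v2[200] + 1.5
  raised <- dhw(make_hotspot(matrix(v2, n, 1), dates))$dhw[, 1]
  expect_true(all(raised - base >= -1e-12, na.rm = TRUE))
  expect_true(all(base <= 84 * max(v) / 7 + 1e-12, na.rm = TRUE))
})

test_that("gap-filled daily input is required", {
  dates <- daily_dates(2000)[-50]
  hs <- make_hotspot(matrix(0, length(dates), 1), dates)
  expect_error(dhw(hs), "gap-free")
})

test_that("austral annual maxima land in the span's ending year", {
  dates <- seq(as.Date("1998-08-01"), as.Date("2001-07-31"), by = "day")
  m <- matrix(0, length(dates), 2)
  m[dates == as.Date("2000-01-15"), 1] <- 9    # January 2000 peak
  m[, 2] <- 1.25                               # constant series
  am <- annual_max_dhw(make_dhw_series(m, dates))
  expect_equal(am$years, 1999:2001)
  expect_equal(unname(am$annual_max[am$years == 2000, 1]), 9)
  expect_equal(unname(am$annual_max[am$years != 2000, 1]), c(0, 0))
  expect_equal(unname(am$annual_max[, 2]), rep(1.25, 3))
})

test_that("partial austral years are dropped with a warning", {
  dates <- seq(as.Date("1999-01-01"), as.Date("2001-07-31"), by = "day")
  m <- matrix(1, length(dates), 1)
  m[1:83, ] <- NA                              # DHW warm-up
  expect_warning(am <- annual_max_dhw(make_dhw_series(m, dates)), "partial")
  expect_equal(am$years, 2000:2001)            # 1999 span starts Aug 1998
})

test_that("annual maxima match a brute-force date filter", {
  set.seed(9)
  dates <- seq(as.Date("1997-08-01"), as.Date("2000-07-31"), by = "day")
  m <- matrix(runif(length(dates) * 3, 0, 10), ncol = 3)
  am <- annual_max_dhw(make_dhw_series(m, dates))
  for (y in am$years) {
    span <- dates >= as.Date(paste0(y - 1, "-08-01")) &
      dates <= as.Date(paste0(y, "-07-31"))
    expect_equal(am$annual_max[am$years == y, ],
                 apply(m[span, , drop = FALSE], 2, max))
  }
})

test_that("spatial and ensemble aggregation follow the median convention", {
  am <- make_annual_max(matrix(c(1, 2, 9), 1, 3), 2000L)
  expect_equal(unname(grid_median(am)), 2)
  am_eq <- make_annual_max(matrix(5, 2, 4), 2000:2001)
  expect_equal(unname(grid_median(am_eq)), c(5, 5))
  meds <- lapply(1:5, function(k) setNames(rep(k, 2), 2000:2001))
  expect_equal(unname(ensemble_median(meds)), c(3, 3))
  expect_equal(unname(ensemble_median(meds, fun = "median")), c(3, 3))
})
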