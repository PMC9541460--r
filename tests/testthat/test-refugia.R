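test_that("climatological mean DHW averages the classification period", {
  am <- make_annual_max(matrix(4, 21, 3), 1999:2019)
  expect_equal(climatological_mean_dhw(am), rep(4, 3))
  am2 <- make_annual_max(matrix(0:20, 21, 1), 1999:2019)
  expect_equal(climatological_mean_dhw(am2), 10)
  set.seed(5)
  m <- matrix(runif(21 * 6, 0, 12), 21, 6)
  am3 <- make_annual_max(m, 1999:2019)
  oracle <- vapply(1:6, function(j) mean(m[, j]), numeric(1))
  expect_equal(climatological_mean_dhw(am3), oracle)
  am4 <- make_annual_max(m[1:20, , drop = FALSE], 1999:2018)
  expect_error(climatological_mean_dhw(am4), "2019")
})

test_that("the 20th-percentile classifier flags the expected cells", {
  mask100 <- classify_refugia(1:100)
  expect_equal(mask100$threshold_value, 20.8)  # linear-interpolation quantile
  expect_equal(sum(mask100$is_refugium), 20L)
  expect_true(all(which(mask100$is_refugium) == 1:20))

  mask10 <- classify_refugia(1:10)
  expect_equal(mask10$threshold_value, 2.8)
  expect_equal(which(mask10$is_refugium), 1:2)

  expect_warning(tied <- classify_refugia(rep(3, 30)), "every cell")
  expect_true(all(tied$is_refugium))
  expect_error(classify_refugia(c(1, 2, 3)), "at least 5")
})

test_that("refugia fraction tracks the percentile on distinct fields", {
  set.seed(8)
  for (n in c(37, 100, 253)) {
    vals <- sample(seq_len(10 * n), n)   # all distinct
    m <- classify_refugia(vals, percentile = 0.2)
    expect_lte(abs(sum(m$is_refugium) - 0.2 * n), 1)
  }
})

test_that("agreement maps count flagging models per cell", {
  m1 <- make_mask(c(TRUE, TRUE, FALSE, FALSE))
  same <- model_agreement(rep(list(m1), 5))
  expect_true(all(same$n_agree %in% c(0L, 5L)))
  disjoint <- model_agreement(list(
    make_mask(c(TRUE, FALSE, FALSE, FALSE)),
    make_mask(c(FALSE, TRUE, FALSE, FALSE)),
    make_mask(c(FALSE, FALSE, TRUE, FALSE))
  ))
  expect_true(all(disjoint$n_agree <= 1L))
  set.seed(2)
  masks <- lapply(1:5, function(k) make_mask(runif(40) < 0.3))
  agg <- model_agreement(masks)
  oracle <- rowSums(vapply(masks, function(m) m$is_refugium, logical(40)))
  expect_equal(agg$n_agree, as.integer(oracle))
  expect_equal(model_agreement(rev(masks))$n_agree, agg$n_agree)
  expect_error(model_agreement(list(m1, make_mask(c(TRUE, FALSE)))),
               "mismatch")
})

test_that("reference agreement requires both the reference and a quorum", {
  masks <- list(make_mask(c(TRUE, TRUE, FALSE, TRUE)),
                make_mask(c(TRUE, FALSE, FALSE, TRUE)),
                make_mask(c(FALSE, FALSE, FALSE, TRUE)))
  refm <- make_mask(c(TRUE, TRUE, TRUE, FALSE))
  got <- reference_agreement(masks, refm, min_models = 2)
  expect_equal(got, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("persistence re-ranks cells year by year", {
  # stationary field identical to the classification values: fraction 1
  vals <- seq(0.5, 10, length.out = 20)
  am <- make_annual_max(matrix(vals, 8, 20, byrow = TRUE), 2000:2007)
  mask <- classify_refugia(vals)
  p <- persistence(am, mask)
  expect_equal(p$fraction_below, rep(1, 8))

  # force refugia far above everyone in one year: fraction 0 there
  am$annual_max[3, mask$is_refugium] <- 100
  p2 <- persistence(am, mask)
  expect_equal(p2$fraction_below[3], 0)
  expect_equal(p2$fraction_below[-3], rep(1, 7))

  # uniform offsets cannot change a rank-based fraction
  am3 <- am
  am3$annual_max <- am3$annual_max + rep(c(0, 5, -2, 1, 0, 3, 2, 7), 20)
  expect_equal(persistence(am3, mask)$fraction_below, p2$fraction_below)

  # random-walk field vs explicit per-year re-ranking oracle
  set.seed(31)
  rw <- apply(matrix(rnorm(8 * 20), 8, 20), 2, cumsum) + 10
  am4 <- make_annual_max(rw, 2000:2007)
  p4 <- persistence(am4, mask)
  oracle <- apply(rw, 1, function(v) {
    mean(v[mask$is_refugium] <= quantile(v, 0.2, type = 7))
  })
  expect_equal(p4$fraction_below, unname(oracle))

  expect_error(persistence(am, make_mask(rep(FALSE, 20))), "empty")
})
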