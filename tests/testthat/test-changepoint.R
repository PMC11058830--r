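test_that("an unambiguous step is located exactly", {
  y <- c(rep(0, 50), rep(10, 50))
  cp <- detect_change_points(y, "pelt_mean")
  expect_identical(cp$breakpoints, 51L) # first month of the new regime
  bs <- detect_change_points(y, "binseg_mean", max_changepoints = 1L)
  expect_identical(bs$breakpoints, 51L)
})

test_that("PELT equals the exhaustive optimum for a single admissible break", {
  minseg <- 12L
  set.seed(31)
  for (k in 1:30) {
    n <- sample(40:60, 1)
    shift <- sample(c(0, 1, 3), 1) # includes no-change instances
    y <- c(rnorm(n %/% 2), rnorm(n - n %/% 2, shift))
    pen <- 3 * log(n)
    cp <- detect_change_points(y, "pelt_mean", min_segment_length = minseg)
    z <- (y - mean(y)) / hydroscale:::robust_noise_sd(y)
    cost <- hydroscale:::make_mean_cost(z)
    cands <- minseg:(n - minseg)
    split_costs <- vapply(cands, function(b) cost(0, b) + cost(b, n) + pen, 0)
    exhaustive <- if (min(split_costs) < cost(0, n))
      cands[which.min(split_costs)] + 1L else integer(0)
    expect_identical(cp$breakpoints, as.integer(exhaustive))
  }
})

test_that("the number of breakpoints is non-increasing in the penalty", {
  set.seed(5)
  y <- c(rnorm(40), rnorm(40, 3), rnorm(40, -2), rnorm(40, 1))
  counts <- vapply(c(1, 5, 15, 40, 120, 400), function(pen)
    length(detect_change_points(y, "pelt_mean", penalty = pen)$breakpoints), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("segment fits recover exact lines and refuse short segments", {
  y <- 100 - 0.06 * (1:120)
  seg <- fit_segments(y)
  expect_equal(seg[[1]]$slope, -0.06, tolerance = 1e-12)
  expect_equal(seg[[1]]$r_squared, 1)

  # splitting a single line anywhere leaves both slopes unchanged
  seg2 <- fit_segments(y, breakpoints = 47L)
  expect_equal(seg2[[1]]$slope, -0.06, tolerance = 1e-12)
  expect_equal(seg2[[2]]$slope, -0.06, tolerance = 1e-12)

  set.seed(8)
  noise_seg <- fit_segments(rnorm(100))
  expect_lt(noise_seg[[1]]$r_squared, 0.1)

  expect_error(fit_segments(y, breakpoints = c(2L)), "shorter than 3")
  expect_error(fit_segments(1:30, breakpoints = c(40L)), "out of range")
})

test_that("breakpoints carry calendar labels for monthly series", {
  ts <- monthly_ts(c(rep(0, 50), rep(10, 46)), c(2002L, 1L))
  cp <- detect_change_points(ts, "pelt_mean")
  expect_identical(cp$breakpoint_months, "2006-03") # month 51 from 2002-01
})

test_that("three-phase rate changes are recovered at their information limit", {
  # phases: steep decline, flat, slight rise; the first kink (slope change
  # 0.06/month against noise sd ~0.36) is localizable to about +-10 months,
  # the second (0.005/month) only to tens of months — asserted accordingly
  det <- three_phase_trend()
  hits1 <- 0; found2 <- 0
  n_runs <- 100
  for (s in seq_len(n_runs)) {
    set.seed(4000 + s)
    y <- det + rnorm(180, 0, 0.1 * diff(range(det)))
    cp <- detect_change_points(y, "binseg_trend", max_changepoints = 2L)
    expect_length(cp$breakpoints, 2L)
    if (min(abs(cp$breakpoints - 61L)) <= 10L) hits1 <- hits1 + 1
    if (min(abs(cp$breakpoints - 121L)) <= 60L) found2 <- found2 + 1
  }
  expect_gte(hits1 / n_runs, 0.9)
  expect_gte(found2 / n_runs, 0.8)
})

test_that("series too short for segmentation are refused", {
  expect_error(detect_change_points(rnorm(30), "pelt_mean"),
               "too short")
})
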