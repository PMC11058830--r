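test_that("find_extrema identifies strict interior extrema and plateaus", {
  ex <- find_extrema(c(0, 1, 0, -1, 0))
  expect_identical(ex$maxima, 2L)
  expect_identical(ex$minima, 4L)

  expect_length(unlist(find_extrema(c(1, 2, 3, 4))), 0L)

  # plateau maximum contributes one extremum at its midpoint
  exp_ <- find_extrema(c(0, 2, 2, 2, 0))
  expect_identical(exp_$maxima, 3L)

  t <- 0:239
  exs <- find_extrema(sin(2 * pi * t / 12))
  expect_length(exs$maxima, 20L)
  expect_length(exs$minima, 20L)
})

test_that("mean period inverts the extrema-count frequency", {
  t <- 1:240
  mp12 <- mean_period(sin(2 * pi * t / 12))
  expect_equal(mp12$period, 12, tolerance = 0.1)
  mp60 <- mean_period(sin(2 * pi * (1:480) / 60))
  expect_equal(mp60$period, 60, tolerance = 0.1)
  expect_true(is.na(mean_period(1:50)$period))
})

test_that("EMD reconstructs its input and handles degenerate signals", {
  set.seed(11)
  for (i in 1:5) {
    x <- as.numeric(stats::arima.sim(list(ar = 0.5), 240)) + 0.01 * (1:240)
    d <- emd(x)
    recon <- Reduce(`+`, lapply(d$imfs, `[[`, "values"), init = d$residual)
    expect_lt(max(abs(recon - x)), 1e-9)
  }

  ramp <- 2 + 0.3 * (1:50)
  dr <- emd(ramp)
  expect_length(dr$imfs, 0L)
  expect_equal(dr$residual, ramp)

  dc <- emd(rep(1, 50))
  expect_length(dc$imfs, 0L)

  expect_error(emd(c(1, NA, 3, 4, 5, 6, 7, 8, 9, 10)), "gap-free")
})

test_that("a pure tone comes out as the first IMF", {
  t <- 1:240
  x <- sin(2 * pi * t / 12)
  d <- emd(x)
  expect_gt(cor(d$imfs[[1]]$values, x), 0.99)
  expect_lt(stats::sd(d$residual), 0.05 * stats::sd(x))
})

test_that("EEMD with zero noise equals plain EMD bit-for-bit", {
  set.seed(2)
  x <- as.numeric(stats::arima.sim(list(ar = 0.4), 120))
  s0 <- eemd_settings(ensemble_size = 25L, noise_amplitude_ratio = 0,
                      seed = 3L)
  e1 <- eemd(x, s0)
  e2 <- emd(x, s0)
  expect_identical(lapply(e1$imfs, `[[`, "values"),
                   lapply(e2$imfs, `[[`, "values"))
  expect_identical(e1$residual, e2$residual)
})

test_that("EEMD is deterministic under a fixed seed", {
  set.seed(4)
  x <- sin(2 * pi * (1:120) / 12) + rnorm(120, sd = 0.3)
  st <- eemd_settings(ensemble_size = 20L, seed = 99L)
  e1 <- eemd(x, st)
  e2 <- eemd(x, st)
  expect_identical(lapply(e1$imfs, `[[`, "values"),
                   lapply(e2$imfs, `[[`, "values"))
})

test_that("EEMD separates a two-tone signal with trend into scale components", {
  t <- 1:480
  tone12 <- sin(2 * pi * t / 12)
  tone60 <- sin(2 * pi * t / 60)
  x <- tone12 + tone60 + 0.002 * t
  de <- eemd(x, eemd_settings(ensemble_size = 100L, seed = 7L))
  periods <- vapply(de$imfs, `[[`, 0, "mean_period")
  expect_true(any(periods >= 10 & periods <= 14))
  expect_true(any(periods >= 48 & periods <= 72))

  sc <- group_imfs(de)
  expect_gt(cor(sc$c_annual, tone12), 0.9)
  expect_gt(cor(sc$c_interannual, tone60 + 0.002 * t), 0.9)

  # conservation of the grouped partition
  recon <- Reduce(`+`, lapply(de$imfs, `[[`, "values"), init = de$residual)
  expect_equal(sc$c_noise + sc$c_annual + sc$c_interannual, recon,
               tolerance = 1e-12)
  expect_lt(max(abs(recon - x)), 1e-9)

  # IMFs have near-zero mean
  for (im in de$imfs)
    expect_lt(abs(mean(im$values)), 0.05 * stats::sd(x))

  # ordering: mean periods non-decreasing, allowing one averaged inversion
  inversions <- sum(diff(periods[!is.na(periods)]) < 0)
  expect_lte(inversions, 1L)
})

test_that("grouping respects the 6- and 24-month period cutoffs", {
  mk_imf <- function(period, n = 240L)
    structure(list(values = sin(2 * pi * (1:n) / period), index = 1L,
                   n_extrema = 2L * n %/% period, mean_period = period),
              class = "imf")
  d <- structure(list(input = NULL,
                      imfs = list(mk_imf(3), mk_imf(12), mk_imf(30)),
                      residual = rep(0.5, 240),
                      settings = eemd_settings()),
                 class = "decomposition")
  d$imfs[[2]]$index <- 2L; d$imfs[[3]]$index <- 3L
  sc <- group_imfs(d)
  expect_identical(sc$membership$noise, 1L)
  expect_identical(sc$membership$annual, 2L)
  expect_identical(sc$membership$interannual, 3L)
  expect_identical(sc$membership$residual_in, "interannual")
  # boundary values: T = 6 is annual, T = 24 is interannual
  d2 <- d
  d2$imfs <- list(mk_imf(6), mk_imf(24))
  d2$imfs[[2]]$index <- 2L
  sc2 <- group_imfs(d2)
  expect_identical(sc2$membership$annual, 1L)
  expect_identical(sc2$membership$interannual, 2L)
})
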