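test_that("lag and accumulation transforms follow their window conventions", {
  expect_identical(lag_series(1:5, 0L), 1:5)
  expect_equal(lag_series(c(1, 2, 3, 4), 1L), c(NA, 1, 2, 3))
  expect_error(lag_series(1:4, 4L), "smaller")

  expect_equal(accumulate_series(rep(1, 6), 3L), c(NA, NA, 3, 3, 3, 3))
  expect_identical(accumulate_series(1:5, 0L), 1:5)
  expect_identical(accumulate_series(1:5, 1L), 1:5) # one-month window
  expect_error(accumulate_series(1:4, 9L), "smaller")

  # exact lagged construction: r = 1 at the true lag
  set.seed(1)
  x <- rnorm(100)
  y <- lag_series(x, 3L)
  g <- tl_ta_search(y, x, max_lag = 3L, max_accum = 0L, min_n = 20L)
  expect_identical(g$best$lag, 3L)
  expect_equal(g$best$r, 1, tolerance = 1e-12)
})

test_that("partial correlation reduces to Pearson and matches the matrix oracle", {
  set.seed(21)
  y <- rnorm(60); x <- rnorm(60)
  expect_equal(partial_correlation(y, x)$r, cor(y, x), tolerance = 1e-12)

  for (k in 1:100) {
    n <- sample(20:60, 1)
    nc <- sample(1:3, 1)
    z <- replicate(nc, rnorm(n), simplify = FALSE)
    base <- rnorm(n)
    yy <- base + rnorm(n) + Reduce(`+`, z)
    xx <- base + rnorm(n) + Reduce(`+`, z)
    expect_equal(partial_correlation(yy, xx, z)$r,
                 hydroscale:::partial_correlation_matrix(yy, xx, z),
                 tolerance = 1e-10)
  }

  const <- rep(1, 30)
  r <- partial_correlation(rnorm(30), const)
  expect_true(r$degenerate)
})

test_that("controlling for the common driver removes a spurious correlation", {
  # y depends only on z; x is independent; r(y, x | z) should be null
  crit <- qnorm(0.975) / sqrt(200 - 3 - 3) # Fisher-z critical value, approx
  hits <- 0
  for (s in 1:200) {
    set.seed(6000 + s)
    z <- rnorm(200)
    y <- z + rnorm(200)
    x <- rnorm(200)
    if (abs(partial_correlation(y, x, list(z))$r) < crit) hits <- hits + 1
  }
  expect_gt(hits / 200, 0.9)
  expect_lt(hits / 200, 1)
})

test_that("the TL/TA grid search is invariant to affine rescaling", {
  set.seed(33)
  x <- as.numeric(stats::arima.sim(list(ar = 0.4), 200))
  y <- lag_series(accumulate_series(x, 2L), 1L) + rnorm(200, sd = 0.5)
  g1 <- tl_ta_search(y, x)
  g2 <- tl_ta_search(5 - 2 * y, 100 + 7 * x)
  expect_identical(g1$best$lag, g2$best$lag)
  expect_identical(g1$best$accum, g2$best$accum)
  expect_equal(abs(g1$best$r), abs(g2$best$r), tolerance = 1e-10)
})

test_that("ties break toward the smaller lag + accumulation", {
  # TA-0 and TA-1 are the same transform, so their cells tie exactly;
  # the reported best must be the TA-0 cell
  set.seed(44)
  x <- rnorm(150)
  y <- x + rnorm(150, sd = 0.1)
  g <- tl_ta_search(y, x)
  expect_identical(g$best$lag, 0L)
  expect_identical(g$best$accum, 0L)
  expect_equal(g$r["TL-0", "TA-0"], g$r["TL-0", "TA-1"], tolerance = 1e-12)
})

test_that("planted lag/accumulation couplings are recovered with correct signs", {
  sys <- gen_coupled_system(notrend_config(seed = 314L))
  best <- recover_couplings(sys)
  expect_identical(c(best$precipitation$lag, best$precipitation$accum), c(3L, 0L))
  expect_identical(c(best$ndvi$lag, best$ndvi$accum), c(0L, 3L))
  expect_identical(c(best$temperature$lag, best$temperature$accum), c(0L, 0L))
  expect_gt(best$precipitation$r, 0)
  expect_lt(best$ndvi$r, 0)
  expect_gt(best$temperature$r, 0)
})

test_that("component coupling handles identity predictors and index mismatches", {
  n <- 120
  mk_sc <- function(v) structure(list(c_annual = v, c_interannual = v),
                                 class = "scale_components")
  set.seed(9)
  a <- as.numeric(stats::arima.sim(list(ar = 0.3), n))
  b <- as.numeric(stats::arima.sim(list(ar = 0.3), n))
  comps <- list(level = mk_sc(a), ndvi = mk_sc(a), temp = mk_sc(b))
  tbl <- component_coupling(comps, "annual", response = "level",
                            predictors = c("ndvi", "temp"))
  row <- tbl[tbl$predictor == "ndvi", ]
  expect_identical(c(row$lag, row$accum), c(0L, 0L))
  expect_equal(row$r, 1, tolerance = 1e-10)

  comps$temp <- mk_sc(b[1:100])
  expect_error(component_coupling(comps, "annual", "level", c("ndvi", "temp")),
               "common monthly index")
})

test_that("shuffled-year surrogates are mostly non-significant", {
  # block permutation by whole years breaks the coupling but keeps
  # within-year seasonality; best-cell p is selection-biased so a plain 5%
  # bound does not apply — the check is that clearly dependent series pass
  # and independent ones mostly fail at the same threshold
  hits <- 0
  n_null <- 60
  for (s in seq_len(n_null)) {
    set.seed(7000 + s)
    y <- as.numeric(stats::arima.sim(list(ar = 0.3), 240))
    x <- as.numeric(stats::arima.sim(list(ar = 0.3), 240))
    g <- tl_ta_search(y, x)
    if (g$best$p >= 0.05) hits <- hits + 1
  }
  # under independence some grids still flag significance (selection effect)
  expect_gt(hits / n_null, 0.5)
  expect_match(tl_ta_search(rnorm(100), rnorm(100))$selection_bias_note,
               "selection-biased")
})

test_that("seasonal curves are normalized, phase-preserving and scale-invariant", {
  t <- 1:48
  x <- sin(2 * pi * (t - 4) / 12) # peaks in July for a January start
  sc <- seasonal_curve(x, start = c(2001L, 1L))
  expect_equal(sum(abs(sc$values)), 1, tolerance = 1e-12)
  expect_identical(sc$peak_month, 7L)

  sc10 <- seasonal_curve(10 * x, start = c(2001L, 1L))
  expect_equal(sc$values, sc10$values, tolerance = 1e-10)

  expect_error(seasonal_curve(x[1:20]), "2 full years")
})
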