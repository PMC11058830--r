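test_that("Theil-Sen slope matches lines, constants and the brute-force oracle", {
  expect_equal(theil_sen(c(1, 2, 3, 4))$slope_monthly, 1)
  expect_equal(theil_sen(rep(5, 10))$slope_monthly, 0)
  expect_equal(theil_sen(c(1, 2, 3))$slope_annual, 12)
  expect_error(theil_sen(c(1, 2)), "3 non-missing")

  brute <- function(v, t) {
    s <- c()
    for (i in seq_along(v)[-length(v)]) for (j in (i + 1):length(v))
      s <- c(s, (v[j] - v[i]) / (t[j] - t[i]))
    stats::median(s)
  }
  set.seed(101)
  for (k in 1:100) {
    n <- sample(6:30, 1)
    v <- rnorm(n)
    if (k %% 3 == 0) v[sample(n, 2)] <- NA # missing months keep their index
    keep <- !is.na(v)
    expect_identical(theil_sen(v)$slope_monthly,
                     brute(v[keep], seq_along(v)[keep]))
  }
})

test_that("Mann-Kendall S, ties and antisymmetry match direct enumeration", {
  expect_identical(mann_kendall(c(1, 2, 3, 4))$s, 6)

  r <- mann_kendall(c(1, 1, 2, 2))
  expect_identical(r$s, 4)
  expect_equal(r$var_s, (4 * 3 * 13 - 2 * (2 * 1 * 9)) / 18)

  enum <- function(v) {
    s <- 0
    for (i in seq_along(v)[-length(v)]) for (j in (i + 1):length(v))
      s <- s + sign(v[j] - v[i])
    s
  }
  set.seed(202)
  for (k in 1:100) {
    n <- sample(4:60, 1)
    v <- sample(round(rnorm(n), sample(0:1, 1))) # coarse rounding makes ties
    a <- mann_kendall(v)
    expect_identical(a$s, enum(v))
    b <- mann_kendall(rev(v)) # time reversal negates S, keeps p
    expect_identical(b$s, -a$s)
    expect_equal(b$p, a$p)
  }

  tied <- mann_kendall(rep(2, 10))
  expect_identical(tied$s, 0)
  expect_identical(tied$p, 1)
})

test_that("trend classes put the boundary in improved/degraded", {
  expect_identical(classify_trend(0.002), "improved")
  expect_identical(classify_trend(0), "stable")
  expect_identical(classify_trend(-0.001), "degraded")
  expect_identical(classify_trend(0.0005), "improved")
  expect_identical(classify_trend(-0.0005), "degraded")
  expect_identical(classify_trend(0.00049), "stable")
})

test_that("CV classes reproduce the volatility table thresholds exactly", {
  expect_identical(coefficient_of_variation(rep(1, 5))$class_label, "Low")
  # classifier at the printed thresholds, boundaries inclusive below
  for (case in list(c(0.22, "High"), c(0.20, "High"),
                    c(0.17, "Relative-high"), c(0.15, "Relative-high"),
                    c(0.12, "Medium"), c(0.10, "Medium"),
                    c(0.07, "Relatively low"), c(0.05, "Relatively low"),
                    c(0.04, "Low")))
    expect_identical(classify_cv(as.numeric(case[1])), case[2])
  # cv computation itself: sd/mean on a constructed triple
  r <- coefficient_of_variation(c(1 - 0.12, 1, 1 + 0.12))
  expect_equal(r$cv, 0.12, tolerance = 1e-12)
  expect_identical(r$class_label, "Medium")
  expect_error(coefficient_of_variation(c(-2, -1, 0)), "non-positive")
})

test_that("vegetation mask applies the inclusive NDVI threshold per growing season", {
  mk_stack <- function(val) raster_stack(array(val, c(24, 3, 3)),
                                         start = c(2001L, 1L))
  expect_true(all(vegetation_mask(mk_stack(0.5))))
  expect_false(any(vegetation_mask(mk_stack(0.05))))
  expect_true(all(vegetation_mask(mk_stack(0.1)))) # boundary is vegetated

  # a single bad year fails every_year but can pass mean_of_years
  a <- array(0.5, c(24, 2, 2))
  a[13:24, 1, 1] <- 0.05
  st <- raster_stack(a, start = c(2001L, 1L))
  expect_false(vegetation_mask(st)[1, 1])
  expect_true(vegetation_mask(st, strictness = "mean_of_years")[1, 1])
})

test_that("water frequency percentages and fractions follow the definition", {
  a <- array(0, c(8, 2, 2))
  a[, 1, 1] <- 1            # permanent
  a[1:4, 1, 2] <- 1         # seasonal, 50%
  st <- raster_stack(a, start = c(2001L, 1L))
  wf <- water_frequency(st)
  expect_equal(wf$frequency[1, 1], 100)
  expect_equal(wf$frequency[1, 2], 50)
  expect_equal(wf$at_risk_fraction, 0.5)

  bad <- raster_stack(array(2, c(4, 2, 2)), start = c(2001L, 1L))
  expect_error(water_frequency(bad), "binary")
})

test_that("pixelwise maps agree with the scalar statistics and partition classes", {
  st <- gen_trend_raster(c(3, 3), matrix(0.001, 3, 3), 0, n_months = 60L,
                         seed = 1L)
  sen <- pixelwise("theil_sen", st)
  expect_equal(sen$slope_monthly, matrix(0.001, 3, 3), tolerance = 1e-12)
  expect_equal(sum(sen$class_percent), 100)

  one <- raster_stack(array(sin(1:60) + 2, c(60, 1, 1)), start = c(2001L, 1L))
  mk <- pixelwise("mann_kendall", one)
  expect_equal(mk$s[1, 1], mann_kendall(sin(1:60) + 2)$s)

  # a pixel missing >10% of steps is excluded and percentages still sum to 100
  a <- array(rnorm(60 * 2 * 2) + 5, c(60, 2, 2))
  a[1:30, 2, 2] <- NA
  stm <- raster_stack(a, start = c(2001L, 1L))
  cv <- pixelwise("cv", stm, cv_window = NULL)
  expect_true(is.na(cv$cv[2, 2]))
  expect_equal(sum(cv$class_percent), 100)
})
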