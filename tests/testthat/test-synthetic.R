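test_that("a pure 12-month harmonic has one extremum pair per cycle", {
  cfg <- synthetic_config(
    n_months = 24L, seed = 1L,
    harmonics = list(x = list(harmonic_spec(12, 1))),
    trends = list(x = piecewise_trend_spec(slopes = 0)),
    couplings = list(), noise_sd = c(x = 0), ar1 = c(x = 0))
  ts <- gen_multiscale_series(cfg, "x")
  ex <- find_extrema(ts$values)
  expect_length(ex$maxima, 2L)
  expect_length(ex$minima, 2L)
})

test_that("a noise-free positive slope yields a strictly increasing series", {
  cfg <- synthetic_config(
    n_months = 60L, seed = 1L, harmonics = list(),
    trends = list(x = piecewise_trend_spec(slopes = 0.01)),
    couplings = list(), noise_sd = c(x = 0), ar1 = c(x = 0))
  ts <- gen_multiscale_series(cfg, "x")
  expect_true(all(diff(ts$values) > 0))
})

test_that("identical config and seed give bit-identical systems", {
  a <- gen_coupled_system(synthetic_config(seed = 42L, n_months = 120L))
  b <- gen_coupled_system(synthetic_config(seed = 42L, n_months = 120L))
  for (v in names(a$series))
    expect_identical(a$series[[v]]$values, b$series[[v]]$values)
  c2 <- gen_coupled_system(synthetic_config(seed = 43L, n_months = 120L))
  expect_false(identical(a$series$level$values, c2$series$level$values))
})

test_that("noise-free coupling reproduces the lagged driver exactly", {
  cfg <- synthetic_config(
    seed = 1L, n_months = 60L,
    harmonics = list(precipitation = list(harmonic_spec(12, 15))),
    trends = list(precipitation = piecewise_trend_spec(slopes = 0),
                  level = piecewise_trend_spec(slopes = 0)),
    couplings = list(level = list(coupling_spec("precipitation", 1, lag = 3L))),
    noise_sd = c(precipitation = 0), ar1 = c(precipitation = 0, level = 0),
    response_noise_ratio = 0)
  sys <- gen_coupled_system(cfg)
  lev <- sys$series$level$values
  pre <- sys$series$precipitation$values
  expect_equal(lev[4:60], pre[1:57], tolerance = 1e-12)
})

test_that("couplings referencing unknown drivers are rejected", {
  cfg <- synthetic_config(seed = 1L, n_months = 60L,
                          couplings = list(level = list(coupling_spec("runoff", 1))))
  expect_error(gen_coupled_system(cfg), "unknown driver")
})

test_that("generated minus deterministic part leaves AR(1) noise of the requested persistence", {
  cfg <- synthetic_config(n_months = 480L, seed = 9L)
  ts <- gen_multiscale_series(cfg, "ndvi")
  det <- hydroscale:::eval_harmonics(cfg$harmonics$ndvi, 480L) +
    hydroscale:::eval_trend(cfg$trends$ndvi, 480L)
  resid <- ts$values - det
  expect_lt(abs(stats::acf(resid, plot = FALSE)$acf[2] - cfg$ar1[["ndvi"]]), 0.1)
})

test_that("ground truth is written alongside the data", {
  d <- tempfile()
  sys <- gen_coupled_system(synthetic_config(seed = 5L, n_months = 60L))
  write_system(sys, d)
  expect_true(file.exists(file.path(d, "level.csv")))
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = FALSE)
  lags <- vapply(truth$couplings$level, function(cp) cp$lag, 1L)
  expect_true(3L %in% lags)
})

test_that("trend rasters realize the requested slope and CV", {
  st0 <- gen_trend_raster(c(3, 3), slope_field = 0, cv_target_field = 0,
                          n_months = 24L, seed = 1L)
  expect_equal(max(st0$data) - min(st0$data), 0)

  st1 <- gen_trend_raster(c(2, 2), slope_field = 0.001, cv_target_field = 0,
                          n_months = 120L, seed = 1L)
  expect_equal(theil_sen(st1$data[, 1, 1])$slope_monthly, 0.001,
               tolerance = 1e-12)

  st2 <- gen_trend_raster(c(2, 2), slope_field = 0, cv_target_field = 0.25,
                          n_months = 240L, seed = 3L)
  cv <- coefficient_of_variation(st2$data[, 1, 1])$cv
  expect_lt(abs(cv - 0.25), 0.05)

  expect_error(gen_trend_raster(c(2, 2), 0, 0, n_months = 0L), "positive")
})

test_that("water stacks honor the permanent/fringe construction", {
  full <- gen_water_stack(c(12, 12), n_months = 24L, permanent_fraction = 1,
                          seed = 1L)
  wf_full <- water_frequency(full)
  expect_true(all(wf_full$frequency[wf_full$wet_ever] == 100))

  st <- gen_water_stack(c(24, 24), n_months = 120L, permanent_fraction = 0.8,
                        fringe_fraction = 0.5, seed = 2L)
  wf <- water_frequency(st)
  n_wet <- sum(wf$wet_ever)
  expect_identical(sum(wf$permanent), as.integer(round(0.8 * n_wet)))

  fringe_freq <- wf$frequency[wf$wet_ever & !wf$permanent]
  expect_lt(abs(mean(fringe_freq) / 100 - 0.5), 0.05)

  expect_error(gen_water_stack(c(8, 8), permanent_fraction = 1.2), "fractions")
})
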