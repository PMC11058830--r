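# Shared fixtures, built in code at test time.

# coupled system with all piecewise trends flattened: the configuration used
# by the lag/accumulation recovery experiments, where the couplings are the
# only deterministic structure beyond the seasonal harmonics
notrend_config <- function(seed, n_months = 480L) {
  synthetic_config(
    seed = seed, n_months = n_months,
    trends = list(
      temperature = piecewise_trend_spec(slopes = 0, intercept = 8),
      precipitation = piecewise_trend_spec(slopes = 0, intercept = 25),
      ndvi = piecewise_trend_spec(slopes = 0, intercept = 0.3),
      level = piecewise_trend_spec(slopes = 0, intercept = 1048),
      area = piecewise_trend_spec(slopes = 0, intercept = 1000)))
}

# three-phase decline/stable/rise trend mimicking a multi-decade lake-level
# history; breaks at months 61 and 121 of 180
three_phase_trend <- function(n = 180L) {
  hydroscale:::eval_trend(
    piecewise_trend_spec(breakpoints = c(61L, 121L),
                         slopes = c(-0.06, 0, 0.005), intercept = 10),
    n)
}

# write a small series CSV and return its path
write_test_csv <- function(dates, values) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(date = dates, value = values), path,
                   row.names = FALSE, quote = FALSE)
  path
}

# two-pass TL/TA recovery of the planted level couplings; returns the best
# cells and correlation signs per predictor
recover_couplings <- function(system, preds = c("temperature", "precipitation", "ndvi"),
                              response = "level") {
  s <- lapply(system$series, function(x) x$values)
  pass1 <- lapply(preds, function(p)
    tl_ta_search(s[[response]], s[[p]],
                 controls = unname(s[setdiff(preds, p)]))$best)
  names(pass1) <- preds
  tr <- lapply(preds, function(p)
    hydroscale:::tl_ta_transform(s[[p]], pass1[[p]]$lag, pass1[[p]]$accum))
  names(tr) <- preds
  out <- lapply(preds, function(p)
    tl_ta_search(s[[response]], s[[p]],
                 controls = unname(tr[setdiff(preds, p)]))$best)
  names(out) <- preds
  out
}
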