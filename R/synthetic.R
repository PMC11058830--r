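# Synthetic monthly systems with known ground truth: harmonics, piecewise
# trends with reversals, AR(1) noise, lag/accumulation couplings, and raster
# stacks with prescribed slope and CV fields. These stand in for the real
# lake/climate/vegetation inputs in every recovery test.

#' Harmonic component specification
#' @param period period in months (> 0).
#' @param amplitude amplitude (>= 0), in the variable's units.
#' @param phase phase in radians.
#' @export
harmonic_spec <- function(period, amplitude, phase = 0) {
  if (period <= 0) stop("period must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(period = period, amplitude = amplitude, phase = phase),
            class = "harmonic_spec")
}

#' Piecewise-linear trend specification
#'
#' Emulates multi-phase regimes such as a decline-stable-increase lake-level
#' history. \code{breakpoints} are 1-based indices of the first month of each
#' new segment; slopes are per month, one per segment (= breakpoints + 1).
#' The trend is continuous across breaks.
#'
#' @param breakpoints strictly increasing integer indices, inside (1, n).
#' @param slopes numeric, length \code{length(breakpoints) + 1}, units/month.
#' @param intercept value at the first month.
#' @export
piecewise_trend_spec <- function(breakpoints = integer(0), slopes = 0,
                                 intercept = 0) {
  breakpoints <- as.integer(breakpoints)
  if (is.unsorted(breakpoints, strictly = TRUE)) stop("breakpoints must be strictly increasing")
  if (length(slopes) != length(breakpoints) + 1L)
    stop("need one slope per segment (breakpoints + 1)")
  structure(list(breakpoints = breakpoints, slopes = as.numeric(slopes),
                 intercept = intercept),
            class = "piecewise_trend_spec")
}

eval_trend <- function(spec, n) {
  t <- seq_len(n)
  bounds <- c(1L, spec$breakpoints, n + 1L)
  if (any(spec$breakpoints <= 1L | spec$breakpoints > n))
    stop("breakpoints must lie inside the series")
  y <- numeric(n)
  level <- spec$intercept
  for (s in seq_along(spec$slopes)) {
    idx <- t >= bounds[s] & t < bounds[s + 1L]
    y[idx] <- level + spec$slopes[s] * (t[idx] - bounds[s])
    level <- level + spec$slopes[s] * (bounds[s + 1L] - bounds[s])
  }
  y
}

#' Driver-response coupling specification
#'
#' Linear-additive coupling: the response receives
#' \code{coefficient * accumulate(lag(driver, lag), accumulation)}, i.e. the
#' driver summed over an accumulation window ending \code{lag} months before
#' the response month. Mirrors lagged/cumulative climate forcing of a lake.
#'
#' @param driver driver variable name.
#' @param coefficient linear coefficient.
#' @param lag lag in months (0..12).
#' @param accumulation accumulation window in months (0..12; 0 and 1 both mean
#'   a single-month window).
#' @export
coupling_spec <- function(driver, coefficient, lag = 0L, accumulation = 0L) {
  if (lag < 0L || lag > 12L || accumulation < 0L || accumulation > 12L)
    stop("lag and accumulation must be in 0..12")
  structure(list(driver = driver, coefficient = coefficient,
                 lag = as.integer(lag), accumulation = as.integer(accumulation)),
            class = "coupling_spec")
}

# AR(1) noise with stationary sd `sd`, innovation-scaled
ar1_noise <- function(n, sd, phi) {
  if (sd == 0) return(numeric(n))
  if (phi < 0 || phi >= 1) stop("ar1 coefficient must be in [0, 1)")
  as.numeric(stats::arima.sim(list(ar = if (phi > 0) phi else numeric(0)),
                              n = n, sd = sd * sqrt(1 - phi^2)))
}

#' Synthetic-system configuration
#'
#' Defaults describe a 40-year monthly lake system patterned on an arid-zone
#' watershed: temperature and precipitation with 12-month seasonality and an
#' AR(1) stochastic share of half the seasonal amplitude, NDVI likewise,
#' and lake level/area driven by couplings with known lags/accumulations
#' (precipitation lagged 3 months, NDVI accumulated over 3 months with a
#' negative sign, temperature synchronous) plus a decline-stable-increase
#' piecewise trend. Response noise is AR(1) with sd equal to
#' \code{response_noise_ratio} times the sd of the deterministic coupled
#' signal.
#'
#' @param n_months series length.
#' @param start start month \code{c(year, month)}.
#' @param harmonics named list (per variable) of lists of \code{harmonic_spec}.
#' @param trends named list (per variable) of \code{piecewise_trend_spec}.
#' @param couplings named list (per response) of lists of \code{coupling_spec}.
#' @param noise_sd named numeric, AR(1) stationary sd per driver variable.
#' @param ar1 named numeric, AR(1) coefficient per variable in [0, 1).
#' @param response_noise_ratio response noise sd as a fraction of the sd of
#'   the deterministic coupled signal.
#' @param seed integer seed (mandatory; identical config + seed gives
#'   bit-identical output).
#' @export
synthetic_config <- function(n_months = 480L,
                             start = c(1981L, 1L),
                             harmonics = NULL,
                             trends = NULL,
                             couplings = NULL,
                             noise_sd = NULL,
                             ar1 = NULL,
                             response_noise_ratio = 0.3,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(harmonics)) harmonics <- list(
    temperature   = list(harmonic_spec(12, 10, phase = -pi / 2)),
    precipitation = list(harmonic_spec(12, 15, phase = -2 * pi / 3)),
    ndvi          = list(harmonic_spec(12, 0.15, phase = -5 * pi / 6)))
  if (is.null(trends)) trends <- list(
    temperature   = piecewise_trend_spec(slopes = 0.002, intercept = 8),
    precipitation = piecewise_trend_spec(slopes = 0, intercept = 25),
    ndvi          = piecewise_trend_spec(slopes = 0.0002, intercept = 0.3),
    level = piecewise_trend_spec(
      breakpoints = as.integer(round(c(n_months / 3, 2 * n_months / 3))),
      slopes = c(-0.06, 0, 0.005), intercept = 1048),
    area = piecewise_trend_spec(
      breakpoints = as.integer(round(c(n_months / 3, 2 * n_months / 3))),
      slopes = c(-1.67, 0, 0.14), intercept = 1000))
  if (is.null(couplings)) couplings <- list(
    level = list(coupling_spec("temperature", 0.05, lag = 0L, accumulation = 0L),
                 coupling_spec("precipitation", 0.03, lag = 3L, accumulation = 0L),
                 coupling_spec("ndvi", -3, lag = 0L, accumulation = 3L)),
    area = list(coupling_spec("temperature", 1.5, lag = 0L, accumulation = 0L),
                coupling_spec("precipitation", 0.9, lag = 3L, accumulation = 0L),
                coupling_spec("ndvi", -90, lag = 0L, accumulation = 3L)))
  if (is.null(noise_sd)) noise_sd <- c(temperature = 5, precipitation = 7.5,
                                       ndvi = 0.075)
  if (is.null(ar1)) ar1 <- c(temperature = 0.3, precipitation = 0.3,
                             ndvi = 0.3, level = 0.3, area = 0.3)
  structure(list(n_months = as.integer(n_months), start = as.integer(start),
                 harmonics = harmonics, trends = trends, couplings = couplings,
                 noise_sd = noise_sd, ar1 = ar1,
                 response_noise_ratio = response_noise_ratio,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

var_units <- c(temperature = "degC", precipitation = "mm", ndvi = "",
               level = "m", area = "km2")

unit_of <- function(variable) {
  if (variable %in% names(var_units)) var_units[[variable]] else ""
}

eval_harmonics <- function(specs, n) {
  t <- seq_len(n)
  y <- numeric(n)
  for (h in specs) y <- y + h$amplitude * sin(2 * pi * t / h$period + h$phase)
  y
}

# deterministic per-variable sub-seed so single-variable generation matches
# the same variable inside the full system
var_seed <- function(seed, variable) {
  (seed + sum(utf8ToInt(variable)) * 10007L) %% .Machine$integer.max
}

#' Generate one multiscale driver series
#'
#' value(t) = sum of harmonics + piecewise trend + AR(1) noise. Deterministic
#' for a given config + seed; the same variable generated alone or inside
#' \code{gen_coupled_system} is identical.
#'
#' @param config a \code{synthetic_config}.
#' @param variable variable name present in the config.
#' @return a \code{monthly_ts}.
#' @export
gen_multiscale_series <- function(config, variable) {
  n <- config$n_months
  det <- eval_harmonics(config$harmonics[[variable]] %||% list(), n) +
    eval_trend(config$trends[[variable]] %||% piecewise_trend_spec(), n)
  sd_v <- if (variable %in% names(config$noise_sd)) config$noise_sd[[variable]] else 0
  noise <- local_seed(var_seed(config$seed, variable),
                      ar1_noise(n, sd_v, config$ar1[[variable]] %||% 0))
  monthly_ts(det + noise, config$start,
             units = unit_of(variable), name = variable)
}

coupled_signal <- function(config, response, drivers) {
  n <- config$n_months
  sig <- numeric(n)
  for (cp in config$couplings[[response]]) {
    if (is.null(drivers[[cp$driver]]))
      stop("coupling for '", response, "' references unknown driver '", cp$driver, "'")
    x <- drivers[[cp$driver]]$values
    z <- accumulate_series(x, cp$accumulation)
    z <- lag_series(z, cp$lag)
    sig <- sig + cp$coefficient * ifelse(is.na(z), 0, z)
  }
  sig
}

#' Generate the full coupled system
#'
#' Drivers (temperature, precipitation, NDVI) are generated by
#' \code{gen_multiscale_series}; each response (level, area) is the linear
#' combination of its lagged/accumulated drivers plus its piecewise trend plus
#' AR(1) noise scaled to \code{response_noise_ratio} times the coupled-signal
#' sd. The generating truth travels with the data.
#'
#' @param config a \code{synthetic_config}.
#' @return list with \code{series} (named list of \code{monthly_ts}) and
#'   \code{truth} (the coupling specs and trend specs used).
#' @export
gen_coupled_system <- function(config) {
  driver_names <- unique(unlist(lapply(config$couplings, function(cps)
    vapply(cps, function(cp) cp$driver, ""))))
  known <- union(names(config$harmonics), names(config$trends))
  if (length(bad <- setdiff(driver_names, known)))
    stop("coupling references unknown driver(s): ", paste(bad, collapse = ", "))
  drivers <- stats::setNames(
    lapply(driver_names, function(v) gen_multiscale_series(config, v)),
    driver_names)
  responses <- list()
  for (resp in names(config$couplings)) {
    n <- config$n_months
    sig <- coupled_signal(config, resp, drivers)
    det <- sig + eval_trend(config$trends[[resp]] %||% piecewise_trend_spec(), n)
    nsd <- config$response_noise_ratio * stats::sd(sig)
    noise <- local_seed(var_seed(config$seed, resp),
                        ar1_noise(n, nsd, config$ar1[[resp]] %||% 0))
    responses[[resp]] <- monthly_ts(det + noise, config$start,
                                    units = unit_of(resp), name = resp)
  }
  list(series = c(drivers, responses),
       truth = list(couplings = config$couplings, trends = config$trends,
                    seed = config$seed))
}

#' Write a generated system plus its ground truth
#'
#' One CSV per variable and a \code{truth.json} sidecar so downstream recovery
#' checks are self-contained.
#'
#' @param system result of \code{gen_coupled_system}.
#' @param dir output directory.
#' @export
write_system <- function(system, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in names(system$series))
    write_series_csv(system$series[[v]], file.path(dir, paste0(v, ".csv")))
  truth <- rapply(system$truth, unclass, how = "list")
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Generate a raster stack with prescribed per-pixel slope and CV
#'
#' Each pixel's series is \code{base + slope * (t - midpoint) + N(0, sigma)},
#' with \code{sigma} chosen so the realized coefficient of variation
#' approximates \code{cv_target_field} (the trend's own variance is accounted
#' for; sigma is floored at 0 when the trend alone exceeds the target).
#'
#' @param shape \code{c(rows, cols)}.
#' @param slope_field per-pixel slope matrix (units/month); scalar recycled.
#' @param cv_target_field per-pixel target CV matrix; scalar recycled.
#' @param n_months stack length (> 0).
#' @param base pixel mean level.
#' @param seed integer seed.
#' @param start \code{c(year, month)} of the first layer.
#' @return a \code{raster_stack}.
#' @export
gen_trend_raster <- function(shape, slope_field, cv_target_field = 0,
                             n_months = 240L, base = 1, seed = 1L,
                             start = c(2001L, 1L)) {
  if (n_months <= 0) stop("n_months must be positive")
  rows <- shape[1L]; cols <- shape[2L]
  slope_field <- matrix(slope_field, rows, cols)
  cv_target_field <- matrix(cv_target_field, rows, cols)
  t <- seq_len(n_months)
  tc <- t - (n_months + 1) / 2
  a <- array(NA_real_, c(n_months, rows, cols))
  local_seed(seed, {
    for (r in seq_len(rows)) for (c in seq_len(cols)) {
      trend_var <- slope_field[r, c]^2 * stats::var(tc)
      sigma2 <- max(0, (cv_target_field[r, c] * base)^2 - trend_var)
      a[, r, c] <- base + slope_field[r, c] * tc +
        stats::rnorm(n_months, 0, sqrt(sigma2))
    }
    a
  }) -> a
  raster_stack(a, start = start, name = "synthetic_trend")
}

#' Generate a binary monthly water stack with permanent core and fringe
#'
#' Wet-ever pixels form a centered disc; the innermost
#' \code{round(permanent_fraction * n_wet)} of them (by distance from the
#' center) are water every month, the remaining fringe pixels are water in a
#' random subset of months with mean occupancy \code{fringe_fraction}
#' (clamped to at least 1 and at most n_months - 1 wet months so fringe
#' frequency is strictly between 0 and 100%).
#'
#' @param shape \code{c(rows, cols)}.
#' @param n_months stack length.
#' @param permanent_fraction fraction of wet-ever pixels that are permanent.
#' @param fringe_fraction mean monthly occupancy of fringe pixels.
#' @param seed integer seed.
#' @param start \code{c(year, month)}.
#' @return a \code{raster_stack} of 0/1 (never-wet pixels are all-zero).
#' @export
gen_water_stack <- function(shape, n_months = 120L, permanent_fraction = 0.8,
                            fringe_fraction = 0.5, seed = 1L,
                            start = c(2001L, 1L)) {
  if (permanent_fraction < 0 || permanent_fraction > 1 ||
      fringe_fraction < 0 || fringe_fraction > 1)
    stop("fractions must be in [0, 1]")
  rows <- shape[1L]; cols <- shape[2L]
  cr <- (rows + 1) / 2; cc <- (cols + 1) / 2
  d <- sqrt(outer((seq_len(rows) - cr)^2, (seq_len(cols) - cc)^2, `+`))
  radius <- 0.45 * min(rows, cols)
  wet_ever <- which(d <= radius)
  if (!length(wet_ever)) stop("grid too small for a water body")
  ord <- wet_ever[order(d[wet_ever])]
  n_perm <- round(permanent_fraction * length(ord))
  permanent <- ord[seq_len(n_perm)]
  fringe <- setdiff(ord, permanent)
  a <- array(0, c(n_months, rows, cols))
  cell_rc <- function(cell) c((cell - 1L) %% rows + 1L, (cell - 1L) %/% rows + 1L)
  for (p in permanent) { rc <- cell_rc(p); a[, rc[1L], rc[2L]] <- 1 }
  local_seed(seed, {
    for (p in fringe) {
      rc <- cell_rc(p)
      k <- stats::rbinom(1L, n_months, fringe_fraction)
      k <- min(max(k, 1L), n_months - 1L)
      wet <- sample.int(n_months, k)
      a[wet, rc[1L], rc[2L]] <- 1
    }
    a
  }) -> a2
  raster_stack(a2, start = start, name = "synthetic_water",
               units = "binary")
}

# run expr under a temporary RNG state, restoring the caller's stream
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
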