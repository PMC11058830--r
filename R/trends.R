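# Robust trend and variability statistics: Theil-Sen median slope,
# Mann-Kendall test with tie correction, coefficient of variation with the
# five-class volatility table, vegetation masking, water-frequency mapping —
# scalar and per-pixel.

#' Theil-Sen median slope
#'
#' The median of all pairwise slopes (x_j - x_i) / (t_j - t_i) over month
#' indices, a robust trend estimator. Missing entries are dropped; their
#' month indices are kept so irregular observation does not bias the slope.
#'
#' @param ts a \code{monthly_ts} or numeric vector.
#' @return list with \code{slope_monthly} (units/month),
#'   \code{slope_annual} (= 12 x monthly), and \code{n}.
#' @export
theil_sen <- function(ts) {
  v <- as_values(ts)
  t <- seq_along(v)
  keep <- !is.na(v)
  v <- v[keep]; t <- t[keep]
  n <- length(v)
  if (n < 3L) stop("theil_sen needs >= 3 non-missing values")
  dv <- outer(v, v, `-`)
  dt <- outer(t, t, `-`)
  slopes <- dv[lower.tri(dv)] / dt[lower.tri(dt)]
  s <- stats::median(slopes)
  list(slope_monthly = s, slope_annual = 12 * s, n = n)
}

#' Mann-Kendall trend test
#'
#' Nonparametric monotonic-trend test: S = sum over pairs i < j of
#' sign(x_j - x_i); Var(S) with the tie-group correction
#' [n(n-1)(2n+5) - sum_g t_g(t_g-1)(2t_g+5)] / 18; z uses the +-1 continuity
#' correction; two-sided normal p-value. With all values tied, S = 0 and
#' p = 1.
#'
#' @param ts a \code{monthly_ts} or numeric vector with >= 4 non-missing
#'   values.
#' @return a list (class \code{trend_result}) with \code{s}, \code{var_s},
#'   \code{z}, \code{p}, \code{n}.
#' @export
mann_kendall <- function(ts) {
  v <- as_values(ts)
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < 4L) stop("mann_kendall needs >= 4 non-missing values")
  # S = sum_{i<j} sign(x_j - x_i); pairs i<j live in the upper triangle
  m <- outer(v, v, function(a, b) sign(b - a))
  s <- sum(m[upper.tri(m)])
  ties <- table(v)
  tie_term <- sum(ties * (ties - 1) * (2 * ties + 5))
  var_s <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  z <- if (var_s == 0) 0
  else if (s > 0) (s - 1) / sqrt(var_s)
  else if (s < 0) (s + 1) / sqrt(var_s)
  else 0
  p <- if (var_s == 0) 1 else 2 * stats::pnorm(-abs(z))
  structure(list(s = s, var_s = var_s, z = z, p = p, n = n),
            class = "trend_result")
}

#' Classify an annual trend slope
#'
#' Improved / stable / degraded classes with a symmetric threshold. The field
#' convention puts the boundary value in the improved (degraded) class:
#' slope >= threshold is improved, slope <= -threshold is degraded, strictly
#' between is stable.
#'
#' @param annual_slope slope in units/year.
#' @param threshold class boundary (units/year).
#' @return "improved", "stable" or "degraded".
#' @export
classify_trend <- function(annual_slope, threshold = 0.0005) {
  if (!is.finite(annual_slope)) stop("slope must be finite")
  if (annual_slope >= threshold) "improved"
  else if (annual_slope <= -threshold) "degraded"
  else "stable"
}

cv_breaks <- c(-Inf, 0.05, 0.10, 0.15, 0.20, Inf)
cv_labels <- c("Low", "Relatively low", "Medium", "Relative-high", "High")

#' Volatility class of a coefficient of variation
#'
#' Classes: cv >= 0.20 High; [0.15, 0.20) Relative-high; [0.10, 0.15) Medium;
#' [0.05, 0.10) Relatively low; < 0.05 Low. Lower bounds are inclusive.
#'
#' @param cv coefficient of variation (>= 0).
#' @return the class label.
#' @export
classify_cv <- function(cv) {
  if (!is.finite(cv) || cv < 0) stop("cv must be finite and >= 0")
  cv_labels[findInterval(cv, cv_breaks[-1L]) + 1L]
}

#' Coefficient of variation with volatility class
#'
#' cv = sample standard deviation / mean (requires a positive mean, as for
#' NDVI). Classes: cv >= 0.20 High; [0.15, 0.20) Relative-high;
#' [0.10, 0.15) Medium; [0.05, 0.10) Relatively low; < 0.05 Low.
#'
#' @param values numeric vector (>= 3 values), e.g. yearly growing-season
#'   means of NDVI.
#' @return list with \code{cv}, \code{class_label}, \code{n}.
#' @export
coefficient_of_variation <- function(values) {
  v <- as_values(values)
  v <- v[!is.na(v)]
  if (length(v) < 3L) stop("coefficient_of_variation needs >= 3 values")
  m <- mean(v)
  if (m <= 0) stop("coefficient of variation undefined for non-positive mean")
  cv <- stats::sd(v) / m
  list(cv = cv, class_label = classify_cv(cv), n = length(v))
}

#' Yearly aggregation of a series over a calendar window
#'
#' Means of the in-window values per year — the usual input to the CV
#' volatility classification (one growing-season mean per year).
#'
#' @param ts a \code{monthly_ts}.
#' @param window a \code{calendar_window}; default the growing season.
#' @return named numeric vector, one mean per year.
#' @export
yearly_window_means <- function(ts, window = growing_season()) {
  groups <- season_subset(ts, window)
  vapply(groups, function(v) mean(v, na.rm = TRUE), 0)
}

#' Stable-vegetation mask from an NDVI stack
#'
#' A pixel is stable vegetation when its growing-season mean NDVI reaches the
#' threshold (inclusive) — in every year (\code{strictness = "every_year"},
#' default) or on the mean across years (\code{"mean_of_years"}).
#'
#' @param ndvi_stack a \code{raster_stack} of NDVI.
#' @param window growing-season \code{calendar_window}.
#' @param threshold NDVI threshold (inclusive).
#' @param strictness "every_year" or "mean_of_years".
#' @return logical matrix (rows x cols).
#' @export
vegetation_mask <- function(ndvi_stack, window = growing_season(),
                            threshold = 0.1,
                            strictness = c("every_year", "mean_of_years")) {
  strictness <- match.arg(strictness)
  mo <- stack_month_of(ndvi_stack)
  yr <- stack_year_of(ndvi_stack)
  keep <- mo %in% window_months(window)
  if (!any(keep)) stop("stack does not cover the window")
  yrs <- unique(yr[keep])
  d <- dim(ndvi_stack$data)
  yearly <- array(NA_real_, c(length(yrs), d[2L], d[3L]))
  for (i in seq_along(yrs)) {
    sel <- keep & yr == yrs[i]
    yearly[i, , ] <- apply(ndvi_stack$data[sel, , , drop = FALSE], c(2L, 3L),
                           mean, na.rm = TRUE)
  }
  if (strictness == "every_year")
    apply(yearly, c(2L, 3L), function(v) all(!is.na(v) & v >= threshold))
  else
    apply(yearly, c(2L, 3L), function(v) mean(v, na.rm = TRUE) >= threshold)
}

#' Water-frequency map from a binary monthly stack
#'
#' Per-pixel frequency = 100 x (months classified water) / (valid months in
#' the window). Permanent water is frequency exactly 100%; the at-risk
#' fraction is the share of wet-ever pixels with 0 < frequency < 100.
#'
#' @param water_stack a \code{raster_stack} with values in {0, 1} (NA allowed).
#' @param window optional \code{calendar_window} restriction.
#' @return list with \code{frequency} (percent matrix), \code{permanent}
#'   (logical matrix), \code{wet_ever} (logical matrix),
#'   \code{permanent_fraction} and \code{at_risk_fraction} (of wet-ever
#'   pixels).
#' @export
water_frequency <- function(water_stack, window = NULL) {
  vals <- water_stack$data
  if (!all(vals %in% c(0, 1) | is.na(vals)))
    stop("water stack must be binary (0/1)")
  sel <- rep(TRUE, n_months_of(water_stack))
  if (!is.null(window)) sel <- stack_month_of(water_stack) %in% window_months(window)
  sub <- vals[sel, , , drop = FALSE]
  wet <- apply(sub, c(2L, 3L), function(v) sum(v == 1, na.rm = TRUE))
  valid <- apply(sub, c(2L, 3L), function(v) sum(!is.na(v)))
  freq <- ifelse(valid > 0, 100 * wet / valid, NA_real_)
  wet_ever <- !is.na(freq) & freq > 0
  permanent <- !is.na(freq) & freq == 100
  n_wet <- sum(wet_ever)
  list(frequency = freq, permanent = permanent, wet_ever = wet_ever,
       permanent_fraction = if (n_wet) sum(permanent) / n_wet else NA_real_,
       at_risk_fraction = if (n_wet) sum(wet_ever & !permanent) / n_wet else NA_real_)
}

#' Apply a scalar trend statistic per pixel
#'
#' Runs \code{theil_sen}, \code{mann_kendall} or
#' \code{coefficient_of_variation} on every pixel series of a stack, honoring
#' nodata: a pixel missing in more than \code{max_nodata_frac} of time steps
#' is excluded (NA in all output maps). Emits value maps, a class map, and
#' class area percentages over valid pixels.
#'
#' @param op "theil_sen", "mann_kendall" or "cv".
#' @param stack a \code{raster_stack}.
#' @param max_nodata_frac exclusion threshold for per-pixel missingness.
#' @param trend_threshold class boundary for the slope classes (units/year).
#' @param cv_window calendar window for yearly CV aggregation (cv op);
#'   \code{NULL} uses all monthly values.
#' @return list of maps; for "theil_sen": \code{slope_monthly},
#'   \code{slope_annual}, \code{class} and \code{class_percent}; for
#'   "mann_kendall": \code{s}, \code{z}, \code{p}; for "cv": \code{cv},
#'   \code{class}, \code{class_percent}.
#' @export
pixelwise <- function(op = c("theil_sen", "mann_kendall", "cv"), stack,
                      max_nodata_frac = 0.1, trend_threshold = 0.0005,
                      cv_window = growing_season()) {
  op <- match.arg(op)
  d <- dim(stack$data)
  rows <- d[2L]; cols <- d[3L]
  out <- list()
  blank <- matrix(NA_real_, rows, cols)
  class_map <- matrix(NA_character_, rows, cols)
  if (op == "theil_sen") out <- list(slope_monthly = blank, slope_annual = blank)
  if (op == "mann_kendall") out <- list(s = blank, z = blank, p = blank)
  if (op == "cv") out <- list(cv = blank)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    v <- stack$data[, r, c]
    if (mean(is.na(v)) > max_nodata_frac) next
    res <- tryCatch(switch(op,
      theil_sen = theil_sen(v),
      mann_kendall = mann_kendall(v),
      cv = {
        px <- pixel_series(stack, r, c)
        vals <- if (is.null(cv_window)) v else yearly_window_means(px, cv_window)
        coefficient_of_variation(vals)
      }), error = function(e) NULL)
    if (is.null(res)) next
    if (op == "theil_sen") {
      out$slope_monthly[r, c] <- res$slope_monthly
      out$slope_annual[r, c] <- res$slope_annual
      class_map[r, c] <- classify_trend(res$slope_annual, trend_threshold)
    } else if (op == "mann_kendall") {
      out$s[r, c] <- res$s; out$z[r, c] <- res$z; out$p[r, c] <- res$p
    } else {
      out$cv[r, c] <- res$cv
      class_map[r, c] <- res$class_label
    }
  }
  if (op %in% c("theil_sen", "cv")) {
    out$class <- class_map
    valid <- sum(!is.na(class_map))
    levels <- if (op == "theil_sen") c("improved", "stable", "degraded") else cv_labels
    counts <- vapply(levels, function(l) sum(class_map == l, na.rm = TRUE), 0L)
    out$class_percent <- if (valid) 100 * counts / valid else counts * NA_real_
  }
  out
}
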