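# Change-point detection for monthly level/area series and per-segment
# linear rates.
#
# Three methods: pelt_mean — exact penalized optimal partitioning under a
# Gaussian mean-change cost with PELT pruning; binseg_mean — greedy binary
# segmentation on the same cost; binseg_trend — greedy knot placement for a
# continuous piecewise-linear (linear-spline) fit, for regimes that differ in
# rate rather than level. Continuity matters: with unconstrained per-segment
# lines the break position of a slope-only change is nearly unidentifiable
# (a misplaced break costs almost nothing), whereas a misplaced spline knot
# forces lack of fit on both sides. Costs are computed on the series
# standardized by a robust noise-sd estimate (MAD of first differences /
# sqrt(2)) so the default penalty 3*log(n) behaves like the usual
# likelihood-based (MBIC-style) penalty.

# O(1) segment cost from cumulative sums: sum of squared deviations from the
# segment mean of y over (s, t]  (s < t, 0-based s)
make_mean_cost <- function(y) {
  cs <- c(0, cumsum(y)); cs2 <- c(0, cumsum(y^2))
  function(s, t) {
    n <- t - s
    (cs2[t + 1L] - cs2[s + 1L]) - (cs[t + 1L] - cs[s + 1L])^2 / n
  }
}

# per-segment OLS-line RSS in O(1) from cumulative sums
make_trend_cost <- function(y) {
  t <- seq_along(y)
  cs_y <- c(0, cumsum(y)); cs_y2 <- c(0, cumsum(y^2))
  cs_t <- c(0, cumsum(t)); cs_t2 <- c(0, cumsum(t^2))
  cs_ty <- c(0, cumsum(t * y))
  function(s, tt) {
    n <- tt - s
    sy <- cs_y[tt + 1L] - cs_y[s + 1L]
    sy2 <- cs_y2[tt + 1L] - cs_y2[s + 1L]
    st <- cs_t[tt + 1L] - cs_t[s + 1L]
    st2 <- cs_t2[tt + 1L] - cs_t2[s + 1L]
    sty <- cs_ty[tt + 1L] - cs_ty[s + 1L]
    sxx <- st2 - st^2 / n
    sxy <- sty - st * sy / n
    syy <- sy2 - sy^2 / n
    if (sxx <= 0) syy else syy - sxy^2 / sxx
  }
}

robust_noise_sd <- function(y) {
  s <- stats::mad(diff(y)) / sqrt(2)
  if (s == 0) s <- stats::sd(y)
  if (is.na(s) || s == 0) s <- 1
  s
}

# PELT: exact minimization of sum(seg costs) + penalty * (#segments - 1)
pelt <- function(cost, n, penalty, minseg) {
  f <- c(-penalty, rep(Inf, n))
  cp_prev <- integer(n + 1L)
  cands <- 0L
  for (t in seq_len(n)) {
    if (t < minseg) { f[t + 1L] <- Inf; next }
    ok <- cands[t - cands >= minseg]
    vals <- vapply(ok, function(s) f[s + 1L] + cost(s, t) + penalty, 0)
    best <- which.min(vals)
    f[t + 1L] <- vals[best]
    cp_prev[t + 1L] <- ok[best]
    keep <- ok[vals - penalty <= f[t + 1L]]
    young <- cands[t - cands < minseg]  # not yet eligible; keep for later
    cands <- c(keep, young, t)
  }
  bp <- integer(0)
  t <- n
  while (t > 0L) {
    s <- cp_prev[t + 1L]
    if (s > 0L) bp <- c(s, bp)
    t <- s
  }
  bp
}

# continuous linear-spline RSS with slope changes after each knot
kink_rss <- function(y, t, knots) {
  X <- cbind(1, t)
  for (k in knots) X <- cbind(X, pmax(t - k, 0))
  sum(stats::lm.fit(X, y)$residuals^2)
}

# greedy knot addition for the continuous piecewise-linear model, followed by
# coordinate-wise refinement of each knot holding the others fixed
kink_search <- function(y, max_changepoints, minseg, penalty = 0, refine = 2L) {
  n <- length(y)
  t <- seq_len(n)
  knots <- integer(0)
  rss0 <- kink_rss(y, t, knots)
  repeat {
    if (length(knots) >= max_changepoints) break
    cands <- setdiff(minseg:(n - minseg),
                     unlist(lapply(knots, function(k) (k - minseg + 1L):(k + minseg - 1L))))
    if (!length(cands)) break
    rss <- vapply(cands, function(k) kink_rss(y, t, sort(c(knots, k))), 0)
    j <- which.min(rss)
    if (rss0 - rss[j] <= penalty) break
    knots <- sort(c(knots, cands[j]))
    rss0 <- rss[j]
  }
  for (pass in seq_len(refine)) for (i in seq_along(knots)) {
    others <- knots[-i]
    lo <- if (any(others < knots[i])) max(others[others < knots[i]]) + minseg else minseg
    hi <- if (any(others > knots[i])) min(others[others > knots[i]]) - minseg else n - minseg
    if (lo > hi) next
    cands <- lo:hi
    rss <- vapply(cands, function(k) kink_rss(y, t, sort(c(others, k))), 0)
    knots[i] <- cands[which.min(rss)]
    knots <- sort(knots)
  }
  knots
}

# greedy binary segmentation: repeatedly split the segment whose best split
# most reduces the cost, until max_changepoints or no admissible gain
binseg <- function(cost, n, max_changepoints, minseg, penalty = 0) {
  bounds <- c(0L, n)
  repeat {
    if (length(bounds) - 2L >= max_changepoints) break
    best_gain <- -Inf; best_split <- NA_integer_
    for (i in seq_len(length(bounds) - 1L)) {
      s <- bounds[i]; e <- bounds[i + 1L]
      splits <- seq.int(s + minseg, e - minseg)
      if (length(splits) == 0L || splits[1L] > splits[length(splits)]) next
      splits <- splits[splits >= s + minseg & splits <= e - minseg]
      if (!length(splits)) next
      base <- cost(s, e)
      gains <- vapply(splits, function(m) base - cost(s, m) - cost(m, e), 0)
      j <- which.max(gains)
      if (gains[j] > best_gain) { best_gain <- gains[j]; best_split <- splits[j] }
    }
    if (!is.finite(best_gain) || best_gain <= penalty) break
    bounds <- sort(c(bounds, best_split))
  }
  setdiff(bounds, c(0L, n))
}

#' Detect change points in a monthly series
#'
#' @param ts a gap-free \code{monthly_ts} or numeric vector.
#' @param method "pelt_mean" (exact penalized optimal partition, mean-shift
#'   cost), "binseg_mean" (greedy, mean-shift cost) or "binseg_trend"
#'   (greedy knot search for a continuous piecewise-linear fit — rate
#'   changes rather than level changes).
#' @param penalty penalty for pelt_mean / minimum split gain for the binseg
#'   methods, on the standardized-cost scale; \code{NULL} = 3 log(n) for
#'   pelt_mean and 0 for the binseg methods (which then split greedily up to
#'   \code{max_changepoints} while a split improves the fit).
#' @param max_changepoints cap for the binseg methods (ignored by pelt_mean).
#' @param min_segment_length shortest admissible segment, months; the default
#'   (12) forbids sub-annual regimes.
#' @return a \code{change_points} list: \code{breakpoints} (1-based index of
#'   the first month of each new segment), \code{breakpoint_months}
#'   ("YYYY-MM" labels when the input carries a calendar), \code{method},
#'   \code{penalty}, and \code{segments} (per-segment linear fits, see
#'   \code{\link{fit_segments}}).
#' @export
detect_change_points <- function(ts,
                                 method = c("pelt_mean", "binseg_mean", "binseg_trend"),
                                 penalty = NULL, max_changepoints = 5L,
                                 min_segment_length = 12L) {
  method <- match.arg(method)
  v <- as_values(ts)
  if (anyNA(v)) stop("change-point detection requires a gap-free series")
  n <- length(v)
  if (n < 3L * min_segment_length)
    stop("series too short: need >= 3 x min_segment_length months")
  if (is.null(penalty)) penalty <- if (method == "pelt_mean") 3 * log(n) else 0
  z <- (v - mean(v)) / robust_noise_sd(v)
  ends <- switch(method,
                 pelt_mean = pelt(make_mean_cost(z), n, penalty, min_segment_length),
                 binseg_mean = binseg(make_mean_cost(z), n, max_changepoints,
                                      min_segment_length, penalty),
                 binseg_trend = kink_search(z, max_changepoints,
                                            min_segment_length, penalty))
  breakpoints <- as.integer(ends + 1L) # first index of the new segment
  labs <- if (inherits(ts, "monthly_ts")) ym_labels(ts)[breakpoints] else NULL
  structure(list(breakpoints = breakpoints, breakpoint_months = labs,
                 method = method, penalty = penalty,
                 segments = fit_segments(ts, breakpoints)),
            class = "change_points")
}

#' @export
print.change_points <- function(x, ...) {
  cat(sprintf("<change_points> %s: %d breakpoint(s)%s\n", x$method,
              length(x$breakpoints),
              if (length(x$breakpoints))
                paste0(" at ", paste(x$breakpoint_months %||% x$breakpoints,
                                     collapse = ", ")) else ""))
  for (s in x$segments)
    cat(sprintf("  [%d..%d] slope %.4f/month, R^2 %.2f\n",
                s$start, s$end - 1L, s$slope, s$r_squared))
  invisible(x)
}

#' Per-segment linear fits
#'
#' Ordinary least squares of value on month index within each segment defined
#' by the breakpoints (each breakpoint starts a new segment). R-squared of a
#' zero-variance fit is reported as 1 for an exactly-flat segment.
#'
#' @param ts a \code{monthly_ts} or numeric vector.
#' @param breakpoints 1-based first-month indices of new segments.
#' @return list of segment fits: \code{start}, \code{end} (half-open, 1-based),
#'   \code{slope} (units/month), \code{intercept}, \code{r_squared}, \code{n}.
#' @export
fit_segments <- function(ts, breakpoints = integer(0)) {
  v <- as_values(ts)
  n <- length(v)
  breakpoints <- as.integer(breakpoints)
  if (any(breakpoints <= 1L | breakpoints > n))
    stop("breakpoints out of range")
  if (is.unsorted(breakpoints, strictly = TRUE))
    stop("breakpoints must be strictly increasing")
  bounds <- c(1L, breakpoints, n + 1L)
  lapply(seq_len(length(bounds) - 1L), function(i) {
    s <- bounds[i]; e <- bounds[i + 1L]
    if (e - s < 3L) stop("segment shorter than 3 months")
    idx <- s:(e - 1L)
    y <- v[idx]
    fit <- stats::lm.fit(cbind(1, idx), y)
    ssr <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    list(start = s, end = e, slope = unname(fit$coefficients[2L]),
         intercept = unname(fit$coefficients[1L]),
         r_squared = if (sst > 0) 1 - ssr / sst else 1,
         n = length(idx))
  })
}
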