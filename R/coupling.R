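# Partial-correlation coupling between lake response and climate/vegetation
# drivers, with a joint time-lag / time-accumulation (TL-k / TA-m) grid
# search, and seasonal-curve normalization for comparing annual components
# across variables of different units.

#' Lag a series by k months
#'
#' The returned vector aligns the predictor value at t - k with the response
#' at t: position t holds x[t - k]; the first k positions are NA and are
#' dropped pairwise downstream.
#'
#' @param x numeric vector.
#' @param k lag in months (0 = identity).
#' @return numeric vector, same length as x.
#' @export
lag_series <- function(x, k = 0L) {
  k <- as.integer(k)
  if (k < 0L) stop("lag must be >= 0")
  n <- length(x)
  if (k >= n) stop("lag must be smaller than the series length")
  if (k == 0L) return(x)
  c(rep(NA_real_, k), x[seq_len(n - k)])
}

#' Accumulate a series over an m-month window
#'
#' Rolling SUM over the window (t - w + 1)..t with w = max(m, 1): TA-0 and
#' TA-1 both denote a single-month window, so both are the identity. The
#' first w - 1 positions are NA. Correlation is scale-invariant, so sum
#' versus mean accumulation changes no correlation downstream.
#'
#' @param x numeric vector.
#' @param m accumulation months (0 or 1 = identity).
#' @return numeric vector, same length as x.
#' @export
accumulate_series <- function(x, m = 0L) {
  m <- as.integer(m)
  if (m < 0L) stop("accumulation must be >= 0")
  n <- length(x)
  if (m >= n) stop("accumulation must be smaller than the series length")
  w <- max(m, 1L)
  if (w == 1L) return(x)
  cs <- c(0, cumsum(x))
  out <- rep(NA_real_, n)
  out[w:n] <- cs[(w:n) + 1L] - cs[(w:n) - w + 1L]
  out
}

# predictor transformed for a TL-k-TA-m cell: accumulate over m months,
# then shift the window k months earlier
tl_ta_transform <- function(x, lag, accum) lag_series(accumulate_series(x, accum), lag)

#' Partial correlation by residualization
#'
#' Pearson correlation between the OLS residuals of y-on-controls and
#' x-on-controls (intercepts included). With no controls this is the plain
#' Pearson correlation. The p-value comes from
#' t = r sqrt(df / (1 - r^2)) with df = n - 2 - #controls, two-sided.
#'
#' @param y,x numeric vectors (aligned; NAs dropped pairwise across all
#'   inputs).
#' @param controls list of numeric control vectors (possibly empty).
#' @return list with \code{r}, \code{p}, \code{n}, \code{df}.
#' @export
partial_correlation <- function(y, x, controls = list()) {
  mat <- cbind(y, x)
  for (cc in controls) mat <- cbind(mat, cc)
  keep <- stats::complete.cases(mat)
  mat <- mat[keep, , drop = FALSE]
  n <- nrow(mat)
  k <- length(controls)
  df <- n - 2L - k
  if (df < 3L) stop("too few aligned observations for partial correlation")
  if (k == 0L) {
    ry <- mat[, 1L] - mean(mat[, 1L])
    rx <- mat[, 2L] - mean(mat[, 2L])
  } else {
    z <- cbind(1, mat[, -(1:2), drop = FALSE])
    ry <- stats::lm.fit(z, mat[, 1L])$residuals
    rx <- stats::lm.fit(z, mat[, 2L])$residuals
  }
  if (stats::sd(ry) == 0 || stats::sd(rx) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, df = df,
                degenerate = TRUE))
  r <- stats::cor(ry, rx)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tt), df)
  }
  list(r = r, p = p, n = n, df = df, degenerate = FALSE)
}

# partial correlation via the inverse-correlation-matrix identity
# r_xy.z = -Omega_xy / sqrt(Omega_xx * Omega_yy); independent cross-check of
# the residualization route, used in tests
partial_correlation_matrix <- function(y, x, controls = list()) {
  mat <- cbind(y, x)
  for (cc in controls) mat <- cbind(mat, cc)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  om <- solve(stats::cor(mat))
  -om[1L, 2L] / sqrt(om[1L, 1L] * om[2L, 2L])
}

#' Joint time-lag / time-accumulation grid search
#'
#' Evaluates the partial correlation between response and predictor for every
#' (lag, accumulation) combination on a (0..max_lag) x (0..max_accum) grid,
#' controls held fixed, and reports the cell maximizing |r| among cells with
#' at least \code{min_n} aligned observations. Ties break toward the smaller
#' lag + accumulation, then the smaller lag. Best-cell p-values are
#' selection-biased (the maximum over a grid); the result carries a flag
#' saying so.
#'
#' @param response,predictor numeric vectors on a common monthly index.
#' @param controls list of control vectors (already transformed as desired).
#' @param max_lag,max_accum grid bounds in months.
#' @param min_n minimum aligned observations per admissible cell.
#' @return a \code{lag_accum_grid}: matrices \code{r}, \code{p}, \code{n}
#'   ((max_lag+1) x (max_accum+1), rows = lags), \code{best} (lag, accum, r,
#'   p), and \code{selection_bias_note}.
#' @export
tl_ta_search <- function(response, predictor, controls = list(),
                         max_lag = 3L, max_accum = 3L, min_n = 24L) {
  lags <- 0:max_lag; accums <- 0:max_accum
  dims <- c(length(lags), length(accums))
  dn <- list(paste0("TL-", lags), paste0("TA-", accums))
  rmat <- matrix(NA_real_, dims[1L], dims[2L], dimnames = dn)
  pmat <- rmat; nmat <- rmat
  for (i in seq_along(lags)) for (j in seq_along(accums)) {
    px <- tl_ta_transform(predictor, lags[i], accums[j])
    res <- tryCatch(partial_correlation(response, px, controls),
                    error = function(e) NULL)
    if (is.null(res)) next
    rmat[i, j] <- res$r; pmat[i, j] <- res$p; nmat[i, j] <- res$n
  }
  admissible <- !is.na(rmat) & nmat >= min_n
  if (!any(admissible)) stop("no grid cell reaches min_n aligned observations")
  cells <- which(admissible, arr.ind = TRUE)
  score <- abs(rmat[admissible])
  cost <- (lags[cells[, 1L]] + accums[cells[, 2L]]) + lags[cells[, 1L]] / 100
  ord <- order(-score, cost)
  bi <- cells[ord[1L], ]
  structure(list(r = rmat, p = pmat, n = nmat,
                 best = list(lag = lags[bi[1L]], accum = accums[bi[2L]],
                             r = rmat[bi[1L], bi[2L]], p = pmat[bi[1L], bi[2L]],
                             n = nmat[bi[1L], bi[2L]]),
                 max_lag = max_lag, max_accum = max_accum, min_n = min_n,
                 selection_bias_note = paste(
                   "best-cell p-value is the minimum over a grid search and",
                   "is selection-biased; do not read it as a single test")),
            class = "lag_accum_grid")
}

#' @export
print.lag_accum_grid <- function(x, ...) {
  b <- x$best
  cat(sprintf("<lag_accum_grid> best TL-%d-TA-%d: r = %.3f (p = %.3g, n = %d)\n",
              b$lag, b$accum, b$r, b$p, b$n))
  cat("note:", x$selection_bias_note, "\n")
  invisible(x)
}

#' Coupling table for one scale component across predictors
#'
#' For the chosen component (annual or interannual) of each variable, runs
#' the TL/TA grid search of the response against each predictor with the
#' remaining predictors as controls. With \code{controls = "best"} (default)
#' the control transforms are found by one iteration: a first pass searches
#' every predictor with the other predictors untransformed, then the final
#' pass holds each control fixed at its first-pass best (lag, accumulation).
#' \code{controls = "raw"} keeps controls untransformed throughout.
#'
#' @param components named list of \code{scale_components} (response and all
#'   predictors), on a common monthly index.
#' @param component "annual" or "interannual".
#' @param response name of the response variable.
#' @param predictors names of the predictor variables.
#' @param controls "best" or "raw" (how control series are transformed).
#' @param max_lag,max_accum,min_n grid parameters, see \code{tl_ta_search}.
#' @return data.frame with one row per predictor: best lag, accumulation, r,
#'   p, n; plus the per-predictor grids in \code{attr(, "grids")}.
#' @export
component_coupling <- function(components, component = c("annual", "interannual"),
                               response, predictors,
                               controls = c("best", "raw"),
                               max_lag = 3L, max_accum = 3L, min_n = 24L) {
  component <- match.arg(component)
  controls <- match.arg(controls)
  slot <- if (component == "annual") "c_annual" else "c_interannual"
  len <- unique(vapply(components, function(sc) length(sc[[slot]]), 0L))
  if (length(len) != 1L) stop("components are not on a common monthly index")
  series <- lapply(components, function(sc) sc[[slot]])
  y <- series[[response]]
  transformed <- series[predictors]
  if (controls == "best") {
    pass1 <- lapply(predictors, function(p)
      tl_ta_search(y, series[[p]],
                   controls = unname(series[setdiff(predictors, p)]),
                   max_lag = max_lag, max_accum = max_accum, min_n = min_n)$best)
    names(pass1) <- predictors
    transformed <- lapply(predictors, function(p)
      tl_ta_transform(series[[p]], pass1[[p]]$lag, pass1[[p]]$accum))
    names(transformed) <- predictors
  }
  grids <- list()
  rows <- lapply(predictors, function(p) {
    ctrl <- transformed[setdiff(predictors, p)]
    g <- tl_ta_search(y, series[[p]], controls = unname(ctrl),
                      max_lag = max_lag, max_accum = max_accum, min_n = min_n)
    grids[[p]] <<- g
    data.frame(response = response, predictor = p, component = component,
               lag = g$best$lag, accum = g$best$accum,
               r = g$best$r, p_value = g$best$p, n = g$best$n,
               significant = g$best$p < 0.05)
  })
  out <- do.call(rbind, rows)
  attr(out, "grids") <- grids
  out
}

#' Normalized seasonal curve of an annual component
#'
#' Calendar-month means of the annual component across years, normalized on
#' the sum of amplitudes: divided by the sum of their absolute values, so
#' curves of variables with different units and magnitudes are directly
#' comparable (sum of |values| = 1; shape and phase preserved).
#'
#' @param c_annual numeric annual-component values.
#' @param start \code{c(year, month)} of the first value.
#' @return a \code{seasonal_curve}: \code{values} (named, Jan..Dec),
#'   \code{peak_month}, \code{normalization} (the divisor used).
#' @export
seasonal_curve <- function(c_annual, start = c(2001L, 1L)) {
  v <- as_values(c_annual)
  if (length(v) < 24L) stop("seasonal_curve needs >= 2 full years")
  lin <- ym_to_linear(start[1L], start[2L]) + seq_along(v) - 1L
  mo <- as.integer(lin %% 12L + 1L)
  means <- vapply(1:12, function(m) mean(v[mo == m]), 0)
  norm <- sum(abs(means))
  if (norm == 0) stop("annual component is identically zero")
  vals <- means / norm
  names(vals) <- month.abb
  structure(list(values = vals, peak_month = unname(which.max(vals)),
                 normalization = norm),
            class = "seasonal_curve")
}
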