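# Empirical Mode Decomposition and its ensemble version (EEMD), with
# mean-period estimation and grouping of IMFs into noise / annual /
# interannual components.
#
# Sifting uses cubic-spline envelopes through the extrema, mirror-extended at
# the boundaries, and a fixed number of sifting iterations per IMF (the
# Wu-Huang recommendation for ensemble stability) rather than an SD stopping
# threshold.

#' Find strict interior extrema
#'
#' Strict local maxima and minima of a sequence, interior points only.
#' A plateau (run of equal values) bounded by lower (higher) neighbours
#' contributes exactly one maximum (minimum) at the plateau midpoint.
#'
#' @param x numeric vector, length >= 3.
#' @return list with integer index vectors \code{maxima} and \code{minima}.
#' @export
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(maxima = integer(0), minima = integer(0)))
  r <- rle(x)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  maxima <- integer(0); minima <- integer(0)
  if (k >= 3L) {
    for (j in 2:(k - 1L)) {
      v <- r$values
      mid <- (starts[j] + ends[j]) %/% 2L
      if (v[j] > v[j - 1L] && v[j] > v[j + 1L]) maxima <- c(maxima, mid)
      else if (v[j] < v[j - 1L] && v[j] < v[j + 1L]) minima <- c(minima, mid)
    }
  }
  list(maxima = maxima, minima = minima)
}

# Mirror the nearest `n_mirror` extrema beyond each end of the series before
# spline fitting; the standard anti-divergence boundary treatment. Endpoints
# themselves are included as envelope anchors clamped to the signal value.
extend_knots <- function(idx, val, n, n_mirror = 2L) {
  if (!length(idx)) return(list(x = numeric(0), y = numeric(0)))
  kl <- utils::head(seq_along(idx), n_mirror)
  kr <- utils::tail(seq_along(idx), n_mirror)
  left_x <- 2 - rev(idx[kl]); left_y <- rev(val[kl])
  right_x <- 2 * n - rev(idx[kr]); right_y <- rev(val[kr])
  keep_l <- left_x < 1
  keep_r <- right_x > n
  list(x = c(left_x[keep_l], idx, right_x[keep_r]),
       y = c(left_y[keep_l], val, right_y[keep_r]))
}

envelope <- function(idx, val, n) {
  kn <- extend_knots(idx, val, n)
  stats::spline(kn$x, kn$y, xout = seq_len(n), method = "fmm")$y
}

# one sifting pass: subtract the mean envelope; NULL when envelopes cannot be
# built (fewer than 2 maxima or 2 minima)
sift_once <- function(h) {
  ex <- find_extrema(h)
  if (length(ex$maxima) < 2L || length(ex$minima) < 2L) return(NULL)
  upper <- envelope(ex$maxima, h[ex$maxima], length(h))
  lower <- envelope(ex$minima, h[ex$minima], length(h))
  h - (upper + lower) / 2
}

#' EEMD settings
#'
#' @param ensemble_size number of noise-perturbed ensemble members (>= 1).
#' @param noise_amplitude_ratio sd of the added white noise as a fraction of
#'   the input sd; 0 degenerates to plain EMD.
#' @param max_imfs number of IMFs; \code{NULL} = auto, floor(log2 n) - 1.
#' @param sift_count fixed sifting iterations per IMF.
#' @param seed integer seed for the ensemble noise.
#' @export
eemd_settings <- function(ensemble_size = 100L, noise_amplitude_ratio = 0.2,
                          max_imfs = NULL, sift_count = 10L, seed = 1L) {
  if (ensemble_size < 1L) stop("ensemble_size must be >= 1")
  if (noise_amplitude_ratio < 0) stop("noise_amplitude_ratio must be >= 0")
  structure(list(ensemble_size = as.integer(ensemble_size),
                 noise_amplitude_ratio = noise_amplitude_ratio,
                 max_imfs = if (is.null(max_imfs)) NULL else as.integer(max_imfs),
                 sift_count = as.integer(sift_count),
                 seed = as.integer(seed)),
            class = "eemd_settings")
}

auto_max_imfs <- function(n) max(1L, as.integer(floor(log2(n)) - 1L))

as_values <- function(x) if (inherits(x, "monthly_ts")) x$values else as.numeric(x)

# core EMD on a bare numeric vector; returns list of IMF vectors + residual
emd_core <- function(x, max_imfs, sift_count) {
  n <- length(x)
  imfs <- list()
  resid <- x
  while (length(imfs) < max_imfs) {
    ex <- find_extrema(resid)
    if (length(ex$maxima) + length(ex$minima) < 2L) break
    h <- resid
    ok <- TRUE
    for (i in seq_len(sift_count)) {
      h2 <- sift_once(h)
      if (is.null(h2)) { ok <- FALSE; break }
      h <- h2
    }
    if (!ok && i == 1L) break       # not even one pass possible: done
    imfs[[length(imfs) + 1L]] <- h
    resid <- resid - h
  }
  list(imfs = imfs, residual = resid)
}

#' Mean period of an oscillatory component
#'
#' The characteristic period is estimated from the extrema count:
#' \code{T = 2 * L / n_extrema}, where \code{n_extrema} counts maxima plus
#' minima and L is the record length in months. For a pure sinusoid this is
#' exact (one maximum and one minimum per cycle). With fewer than 2 extrema
#' the period is undefined (\code{NA}) — a monotone residual has no period.
#'
#' @param values component values (numeric or \code{monthly_ts}).
#' @param series_length record length in months; defaults to
#'   \code{length(values)}.
#' @return list with \code{n_extrema} and \code{period} (months, NA if
#'   undefined).
#' @export
mean_period <- function(values, series_length = NULL) {
  v <- as_values(values)
  if (is.null(series_length)) series_length <- length(v)
  ex <- find_extrema(v)
  n_ext <- length(ex$maxima) + length(ex$minima)
  list(n_extrema = n_ext,
       period = if (n_ext >= 2L) 2 * series_length / n_ext else NA_real_)
}

finish_decomposition <- function(input, imf_list, residual, settings) {
  n <- length(residual)
  imfs <- lapply(seq_along(imf_list), function(i) {
    mp <- mean_period(imf_list[[i]], n)
    structure(list(values = imf_list[[i]], index = i,
                   n_extrema = mp$n_extrema, mean_period = mp$period),
              class = "imf")
  })
  structure(list(input = input, imfs = imfs, residual = residual,
                 settings = settings),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %d IMFs + residual (n = %d)\n",
              length(x$imfs), length(x$residual)))
  for (im in x$imfs)
    cat(sprintf("  IMF %d: %d extrema, mean period %s months\n", im$index,
                im$n_extrema,
                if (is.na(im$mean_period)) "undefined" else
                  sprintf("%.1f", im$mean_period)))
  invisible(x)
}

#' Empirical Mode Decomposition
#'
#' Decomposes a gap-free series into intrinsic mode functions (IMFs) and a
#' residual by sifting: cubic-spline upper/lower envelopes through the
#' extrema (mirror-extended at the boundaries), subtracting the envelope mean
#' a fixed number of times per IMF. Extraction stops when the residual has
#' fewer than 2 interior extrema or \code{max_imfs} is reached. The additive
#' identity sum(IMFs) + residual = input holds to floating-point tolerance by
#' construction.
#'
#' @param x a \code{monthly_ts} (gap-free) or numeric vector, length >= 10.
#' @param settings an \code{eemd_settings} (ensemble fields ignored).
#' @return a \code{decomposition}.
#' @export
emd <- function(x, settings = eemd_settings()) {
  v <- as_values(x)
  if (anyNA(v)) stop("emd requires a gap-free series; see fill_missing()")
  if (length(v) < 10L) stop("series too short for decomposition")
  k <- settings$max_imfs %||% auto_max_imfs(length(v))
  dec <- emd_core(v, k, settings$sift_count)
  finish_decomposition(x, dec$imfs, dec$residual, settings)
}

#' Ensemble Empirical Mode Decomposition
#'
#' EMD repeated over \code{ensemble_size} copies of the input perturbed with
#' white Gaussian noise of sd \code{noise_amplitude_ratio * sd(x)}; each
#' member is decomposed to a common fixed IMF count and the IMFs are averaged
#' position-wise across members. The residual is defined by subtraction
#' (input - sum of averaged IMFs) so the additive identity is exact despite
#' averaging. Deterministic given the settings seed; a noise ratio of 0
#' returns plain \code{emd(x)} exactly.
#'
#' @param x a \code{monthly_ts} (gap-free) or numeric vector, length >= 10.
#' @param settings an \code{eemd_settings}.
#' @return a \code{decomposition}.
#' @export
eemd <- function(x, settings = eemd_settings()) {
  v <- as_values(x)
  if (anyNA(v)) stop("eemd requires a gap-free series; see fill_missing()")
  if (length(v) < 10L) stop("series too short for decomposition")
  if (settings$ensemble_size < 1L) stop("ensemble_size must be >= 1")
  if (settings$noise_amplitude_ratio == 0) return(emd(x, settings))
  n <- length(v)
  k <- settings$max_imfs %||% auto_max_imfs(n)
  noise_sd <- settings$noise_amplitude_ratio * stats::sd(v)
  acc <- matrix(0, nrow = n, ncol = k)
  local_seed(settings$seed, {
    for (m in seq_len(settings$ensemble_size)) {
      vm <- v + stats::rnorm(n, 0, noise_sd)
      dec <- emd_core(vm, k, settings$sift_count)
      for (j in seq_along(dec$imfs)) acc[, j] <- acc[, j] + dec$imfs[[j]]
      # members that stopped early contribute zeros for the missing slots
    }
  })
  acc <- acc / settings$ensemble_size
  imf_list <- lapply(seq_len(k), function(j) acc[, j])
  # drop trailing all-zero slots never reached by any member
  nz <- vapply(imf_list, function(u) any(u != 0), TRUE)
  if (any(nz)) imf_list <- imf_list[seq_len(max(which(nz)))] else imf_list <- list()
  residual <- v - Reduce(`+`, imf_list, accumulate = FALSE, right = FALSE,
                         init = numeric(n))
  finish_decomposition(x, imf_list, residual, settings)
}

#' Group IMFs into noise, annual and interannual components
#'
#' IMFs with mean period T < \code{noise_below} months are summed into the
#' noise component; \code{noise_below} <= T < \code{annual_upper} into the
#' annual (seasonal) component; T >= \code{annual_upper}, IMFs with undefined
#' period, and the residual into the interannual (trend) component. The three
#' components sum to the reconstruction exactly.
#'
#' @param d a \code{decomposition}.
#' @param noise_below noise/annual cutoff in months.
#' @param annual_upper annual/interannual cutoff in months.
#' @return a \code{scale_components} list with \code{c_noise},
#'   \code{c_annual}, \code{c_interannual}, and \code{membership}.
#' @export
group_imfs <- function(d, noise_below = 6, annual_upper = 24) {
  n <- length(d$residual)
  comp <- list(c_noise = numeric(n), c_annual = numeric(n),
               c_interannual = d$residual)
  membership <- list(noise = integer(0), annual = integer(0),
                     interannual = integer(0), residual_in = "interannual")
  for (im in d$imfs) {
    g <- if (is.na(im$mean_period)) "interannual"
    else if (im$mean_period < noise_below) "noise"
    else if (im$mean_period < annual_upper) "annual"
    else "interannual"
    slot <- c(noise = "c_noise", annual = "c_annual",
              interannual = "c_interannual")[[g]]
    comp[[slot]] <- comp[[slot]] + im$values
    membership[[g]] <- c(membership[[g]], im$index)
  }
  structure(c(comp, list(membership = membership,
                         periods = vapply(d$imfs, function(im)
                           im$mean_period, 0))),
            class = "scale_components")
}

#' @export
print.scale_components <- function(x, ...) {
  cat(sprintf(
    "<scale_components> noise: IMF %s | annual: IMF %s | interannual: IMF %s + residual\n",
    paste(x$membership$noise, collapse = ","),
    paste(x$membership$annual, collapse = ","),
    paste(x$membership$interannual, collapse = ",")))
  invisible(x)
}
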