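# Monthly time-series container and calendar plumbing shared by all stages.
# The month is the atomic time unit throughout; days are never represented.

#' Construct a monthly time series
#'
#' A \code{monthly_ts} is a regularly spaced monthly series: a numeric vector,
#' a start month \code{c(year, month)}, and an explicit missingness mask.
#' Gaps in time are always represented as \code{missing = TRUE} entries, never
#' by dropping index positions, so consecutive entries are exactly one
#' calendar month apart by construction.
#'
#' @param values numeric vector, length >= 2.
#' @param start integer vector \code{c(year, month)} with month in 1..12.
#' @param units free-text units (e.g. "m", "km2", "mm", "degC", "").
#' @param name free-text variable name.
#' @param missing logical mask, same length as \code{values}; \code{NA}s in
#'   \code{values} are folded into the mask automatically.
#' @return an object of class \code{monthly_ts}.
#' @export
monthly_ts <- function(values, start, units = "", name = "", missing = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("monthly_ts needs length >= 2")
  if (length(start) != 2L || start[2L] < 1L || start[2L] > 12L)
    stop("start must be c(year, month) with month in 1..12")
  if (is.null(missing)) missing <- is.na(values)
  missing <- as.logical(missing) | is.na(values)
  if (length(missing) != length(values))
    stop("missing mask length must equal values length")
  values[missing] <- NA_real_
  structure(list(values = values, start = as.integer(start),
                 units = units, name = name, missing = missing),
            class = "monthly_ts")
}

#' @export
length.monthly_ts <- function(x) length(x$values)

#' @export
print.monthly_ts <- function(x, ...) {
  lab <- ym_labels(x)
  cat(sprintf("<monthly_ts '%s'> %d months, %s .. %s%s, %d missing\n",
              x$name, length(x$values), lab[1L], lab[length(lab)],
              if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              sum(x$missing)))
  invisible(x)
}

# ---- calendar helpers -------------------------------------------------------

# months since year 0 ("linear month"); used for all index arithmetic
ym_to_linear <- function(year, month) year * 12L + (month - 1L)

linear_to_ym <- function(lin) c(lin %/% 12L, lin %% 12L + 1L)

#' Calendar labels ("YYYY-MM") for each entry of a monthly series
#' @param ts a \code{monthly_ts}.
#' @return character vector of "YYYY-MM" labels.
#' @export
ym_labels <- function(ts) {
  lin <- ym_to_linear(ts$start[1L], ts$start[2L]) + seq_along(ts$values) - 1L
  sprintf("%04d-%02d", lin %/% 12L, lin %% 12L + 1L)
}

#' Calendar month number (1..12) of each entry
#' @param ts a \code{monthly_ts}.
#' @return integer vector in 1..12.
#' @export
month_of <- function(ts) {
  lin <- ym_to_linear(ts$start[1L], ts$start[2L]) + seq_along(ts$values) - 1L
  as.integer(lin %% 12L + 1L)
}

#' Calendar year of each entry
#' @param ts a \code{monthly_ts}.
#' @return integer vector of years.
#' @export
year_of <- function(ts) {
  lin <- ym_to_linear(ts$start[1L], ts$start[2L]) + seq_along(ts$values) - 1L
  as.integer(lin %/% 12L)
}

parse_ym <- function(s) {
  s <- trimws(as.character(s))
  m <- regmatches(s, regexec("^([0-9]{4})[-/]([0-9]{1,2})([-/][0-9]{1,2})?$", s))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    stop("unparseable year-month date(s): ", paste(utils::head(s[bad], 3L), collapse = ", "))
  yr <- vapply(m, function(g) as.integer(g[2L]), 1L)
  mo <- vapply(m, function(g) as.integer(g[3L]), 1L)
  if (any(mo < 1L | mo > 12L)) stop("month out of 1..12 in date column")
  cbind(year = yr, month = mo)
}

# ---- CSV IO -----------------------------------------------------------------

#' Read a monthly series from CSV
#'
#' The CSV dialect is fixed for unambiguous round trips: comma separators, one
#' header row, ISO "YYYY-MM" (or "YYYY-MM-DD") dates, "." decimals. Months
#' absent from the file become \code{missing = TRUE} entries so the returned
#' index is contiguous.
#'
#' @param path CSV file path.
#' @param date_column,value_column column names.
#' @param units,name metadata for the returned series.
#' @return a \code{monthly_ts} with a contiguous monthly index.
#' @export
read_series_csv <- function(path, date_column = "date", value_column = "value",
                            units = "", name = value_column) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c(date_column, value_column) %in% names(df)))
    stop("CSV lacks column(s): ",
         paste(setdiff(c(date_column, value_column), names(df)), collapse = ", "))
  if (nrow(df) < 2L) stop("CSV has fewer than 2 rows")
  ym <- parse_ym(df[[date_column]])
  lin <- ym_to_linear(ym[, "year"], ym[, "month"])
  if (anyDuplicated(lin))
    stop("duplicate month(s) in ", path, ": ",
         paste(unique(df[[date_column]][duplicated(lin)]), collapse = ", "))
  o <- order(lin)
  lin <- lin[o]
  vals <- as.numeric(df[[value_column]])[o]
  full <- seq(lin[1L], lin[length(lin)])
  out <- rep(NA_real_, length(full))
  out[match(lin, full)] <- vals
  monthly_ts(out, linear_to_ym(full[1L]), units = units, name = name)
}

#' Write a monthly series to CSV
#' @param ts a \code{monthly_ts}.
#' @param path output path.
#' @param digits significant digits used for printing values.
#' @export
write_series_csv <- function(ts, path, digits = 10L) {
  df <- data.frame(date = ym_labels(ts),
                   value = ifelse(ts$missing, NA, signif(ts$values, digits)))
  names(df)[2L] <- if (nzchar(ts$name)) ts$name else "value"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# ---- gap handling -----------------------------------------------------------

#' Fill gaps in a monthly series
#'
#' EEMD and change-point analysis require gap-free input. Two fill methods are
#' provided: \code{"linear"} interpolation in time, and \code{"seasonal_mean"}
#' which replaces a missing month by the mean of the same calendar month in
#' other years. Observed entries are never altered; filling a gap-free series
#' is the identity.
#'
#' @param ts a \code{monthly_ts}.
#' @param method "linear" or "seasonal_mean".
#' @param max_missing_frac refuse if more than this fraction is missing.
#' @return a gap-free \code{monthly_ts}.
#' @export
fill_missing <- function(ts, method = c("linear", "seasonal_mean"),
                         max_missing_frac = 0.2) {
  method <- match.arg(method)
  n <- length(ts$values)
  if (!any(ts$missing)) return(ts)
  if (method == "linear" && (ts$missing[1L] || ts$missing[n]))
    stop("linear fill requires observed first and last entries")
  if (mean(ts$missing) >= max_missing_frac)
    stop(sprintf("refusing to fill: %.0f%% of entries missing (limit %.0f%%)",
                 100 * mean(ts$missing), 100 * max_missing_frac))
  v <- ts$values
  if (method == "linear") {
    v <- stats::approx(which(!ts$missing), v[!ts$missing], xout = seq_len(n))$y
  } else {
    mo <- month_of(ts)
    for (i in which(ts$missing)) {
      same <- !ts$missing & mo == mo[i]
      if (!any(same)) stop("seasonal_mean fill: no observed value for calendar month ", mo[i])
      v[i] <- mean(v[same])
    }
  }
  monthly_ts(v, ts$start, units = ts$units, name = ts$name,
             missing = rep(FALSE, n))
}

# ---- calendar windows -------------------------------------------------------

#' Calendar window of months, inclusive, wrapping allowed
#' @param first_month,last_month integers in 1..12; \code{c(11, 2)} means
#'   November through February.
#' @return a \code{calendar_window}.
#' @export
calendar_window <- function(first_month, last_month) {
  if (first_month < 1L || first_month > 12L || last_month < 1L || last_month > 12L)
    stop("window months must be in 1..12")
  structure(list(first_month = as.integer(first_month),
                 last_month = as.integer(last_month)),
            class = "calendar_window")
}

#' Growing-season window (March through October)
#' @return a \code{calendar_window} covering months 3..10.
#' @export
growing_season <- function() calendar_window(3L, 10L)

window_months <- function(window) {
  if (window$first_month <= window$last_month)
    seq(window$first_month, window$last_month)
  else
    c(seq(window$first_month, 12L), seq(1L, window$last_month))
}

#' Subset a monthly series to a calendar window, grouped by year
#'
#' Returns the values whose calendar month lies in the window, grouped per
#' year. For a wrapping window (e.g. Nov-Feb) the "year" of a group is the
#' year of the window's first month, so a winter spanning the new year is one
#' group.
#'
#' @param ts a \code{monthly_ts}.
#' @param window a \code{calendar_window}.
#' @return named list: one numeric vector of in-window values per (season) year.
#' @export
season_subset <- function(ts, window) {
  mo <- month_of(ts); yr <- year_of(ts)
  keep <- mo %in% window_months(window)
  season_year <- yr
  if (window$first_month > window$last_month) # wrapping: months <= last belong to previous start-year
    season_year[mo <= window$last_month] <- yr[mo <= window$last_month] - 1L
  split(ts$values[keep], season_year[keep])
}
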