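#' Climate series containers and trend testing
#'
#' A `climate_series` is an annual (or monthly) station or grid-cell record:
#' strictly increasing time, one value per step, with a units label and a
#' series id. Trend significance follows the classical Student's-t test for a
#' linear trend: ordinary least-squares slope against year, t = slope / se,
#' two-tailed p on n - 2 degrees of freedom.
#'
#' @name climate_trends
NULL

#' Construct a climate series
#'
#' @param year integer vector of years (strictly increasing for annual
#'   series).
#' @param value numeric measurements (°C, mm, ...); `NA` marks missing.
#' @param month optional integer 1-12 for monthly series.
#' @param units units label (e.g. `"degC"`, `"mm"`).
#' @param id station or grid-cell id.
#' @return a `climate_series` data.frame with attributes `units` and `id`.
#' @export
climate_series <- function(year, value, month = NULL, units = "", id = "series") {
  df <- if (is.null(month)) data.frame(year = as.integer(year), value = value)
        else data.frame(year = as.integer(year), month = as.integer(month),
                        value = value)
  key <- if (is.null(month)) df$year else df$year * 12 + df$month
  if (is.unsorted(key, strictly = TRUE)) stop_named("time steps must be strictly increasing")
  if (!is.null(month) && any(month < 1 | month > 12)) stop_named("month must be in 1..12")
  structure(df, units = units, id = id,
            class = c("climate_series", "data.frame"))
}

#' Read climate series from CSV
#'
#' Expects columns `station_id`, `year`, optional `month`, `value`; returns
#' one `climate_series` per station.
#'
#' @param path CSV path.
#' @param units units label applied to all series.
#' @return named list of `climate_series`.
#' @export
read_climate <- function(path, units = "") {
  if (!file.exists(path)) stop_named("climate file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$station_id), function(d) {
    key <- if (is.null(d$month)) d$year else d$year * 12 + d$month
    d <- d[order(key), ]
    climate_series(d$year, d$value, month = d$month, units = units,
                   id = d$station_id[1])
  })
}

#' Collapse a monthly series to annual values
#'
#' `"mean"` for temperature-like series (annually averaged monthly values),
#' `"sum"` for precipitation totals. A year missing more than `max_missing`
#' months is dropped with a warning; remaining missing months are ignored in
#' the mean and treated as contributing zero information to the sum (the sum
#' is computed over observed months only).
#'
#' @param series a monthly `climate_series`.
#' @param statistic `"mean"` or `"sum"`.
#' @param max_missing maximum missing months per year before the year is
#'   dropped (default 2).
#' @return an annual `climate_series`.
#' @export
annual_from_monthly <- function(series, statistic = c("mean", "sum"),
                                max_missing = 2) {
  statistic <- match.arg(statistic)
  if (nrow(series) == 0) stop_named("empty series")
  if (is.null(series$month)) stop_named("series is not monthly")
  by_year <- split(series, series$year)
  miss <- vapply(by_year, function(d) 12L - sum(!is.na(d$value)), integer(1))
  drop <- miss > max_missing
  if (any(drop))
    warning(sprintf("%d year(s) dropped with > %d missing months: %s",
                    sum(drop), max_missing,
                    paste(names(by_year)[drop], collapse = ", ")), call. = FALSE)
  by_year <- by_year[!drop]
  if (length(by_year) == 0) stop_named("no complete-enough years")
  vals <- vapply(by_year, function(d) {
    v <- d$value[!is.na(d$value)]
    if (statistic == "mean") mean(v) else sum(v)
  }, numeric(1))
  climate_series(as.integer(names(by_year)), unname(vals),
                 units = attr(series, "units"), id = attr(series, "id"))
}

#' Anomalies relative to a baseline period
#'
#' Subtracts the mean of the values in the baseline years; by default the
#' baseline is the full period of record, so the anomalies average to zero.
#'
#' @param series an annual `climate_series`.
#' @param baseline integer vector of baseline years; default all years.
#' @return a `climate_series` of anomalies.
#' @export
compute_anomaly <- function(series, baseline = NULL) {
  baseline <- baseline %||% series$year
  inb <- series$year %in% baseline & !is.na(series$value)
  if (!any(inb)) stop_named("baseline does not intersect the series years")
  climate_series(series$year, series$value - mean(series$value[inb]),
                 month = series$month, units = attr(series, "units"),
                 id = attr(series, "id"))
}

#' Student's-t test for a linear trend
#'
#' Ordinary least-squares regression of value on year; the trend statistic is
#' slope / se(slope) with df = (points used) - 2 and a two-tailed p-value. An
#' exact fit (zero residual variance with nonzero slope) is flagged and given
#' p = 0.
#'
#' @param series a `climate_series` (annual), or a data.frame with `year` and
#'   `value`.
#' @return a `trend_result`: list with `slope` (units/yr), `intercept`,
#'   `t_stat`, `df`, `p_value`, `n_used`, `exact_fit`, and significance flags
#'   `significant_05`, `significant_10`.
#' @export
linear_trend_test <- function(series) {
  keep <- !is.na(series$value)
  x <- series$year[keep]; y <- series$value[keep]
  n <- length(x)
  if (n < 3) stop_named("need >= 3 non-missing points for a trend test")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  sse <- sum(stats::residuals(fit)^2)
  sxx <- sum((x - mean(x))^2)
  df <- n - 2L
  exact_fit <- sse < .Machine$double.eps * max(1, sum(y^2))
  if (exact_fit) {
    # scale-aware zero test: a constant series fits exactly with slope ~ 0
    nonzero <- abs(slope) * diff(range(x)) >
      sqrt(.Machine$double.eps) * max(1, max(abs(y)))
    t_stat <- if (nonzero) Inf * sign(slope) else 0
    p <- if (nonzero) 0 else 1
  } else {
    se <- sqrt(sse / df / sxx)
    t_stat <- slope / se
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(slope = slope, intercept = intercept, t_stat = t_stat,
                 df = df, p_value = p, n_used = n, exact_fit = exact_fit,
                 significant_05 = p < 0.05, significant_10 = p < 0.1,
                 id = attr(series, "id") %||% "series"),
            class = "trend_result")
}

#' Per-cell trend map with a significance mask
#'
#' Runs [linear_trend_test()] on every cell of a gridded collection and masks
#' slopes wherever the trend is not significant at `alpha` (the "only trends
#' significant at p < alpha are shown" convention of trend maps).
#'
#' @param cells named list of `climate_series` (one per grid cell/station).
#' @param alpha significance level for the mask (default 0.1).
#' @return data.frame with `cell`, `slope` (NA where masked), `p_value`,
#'   `masked`; attribute `mask_fraction` gives the fraction masked.
#' @export
grid_trend_mask <- function(cells, alpha = 0.1) {
  res <- lapply(names(cells), function(nm) {
    tr <- linear_trend_test(cells[[nm]])
    data.frame(cell = nm, slope = tr$slope, p_value = tr$p_value,
               masked = tr$p_value >= alpha)
  })
  out <- do.call(rbind, res)
  out$slope[out$masked] <- NA_real_
  attr(out, "mask_fraction") <- mean(out$masked)
  out
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> %s: slope = %.4g /yr, t = %.3g, df = %d, p = %.3g%s\n",
              x$id, x$slope, x$t_stat, x$df, x$p_value,
              if (x$exact_fit) " (exact fit)" else ""))
  invisible(x)
}
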