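#' Annual sea-ice index from daily block concentrations
#'
#' Builds the large-scale sea-ice index from daily sea-ice concentrations of
#' a handful of grid blocks: block values are averaged per day, daily means
#' per calendar month, and the twelve monthly means per year. Averaging
#' month-first (rather than pooling days) keeps unequal month lengths from
#' weighting the annual value. A year missing any month is dropped with a
#' warning rather than reported from partial coverage.
#'
#' @param daily Data frame with columns `date` (ISO-8601 or `Date`),
#'   `block_id` and `concentration_pct` in \[0, 100\].
#' @return An [annual_series()] in percent.
#' @export
sea_ice_index <- function(daily) {
  stopifnot(all(c("date", "block_id", "concentration_pct") %in% names(daily)))
  conc <- as.numeric(daily$concentration_pct)
  if (any(is.na(conc)) || any(conc < 0 | conc > 100)) {
    stop("sea-ice concentrations must lie in [0, 100]")
  }
  date <- as.Date(daily$date)
  day_mean <- tapply(conc, format(date, "%Y-%m-%d"), mean)
  dd <- as.Date(names(day_mean))
  ym <- format(dd, "%Y-%m")
  month_mean <- tapply(as.numeric(day_mean), ym, mean)
  yr <- as.integer(substr(names(month_mean), 1L, 4L))
  n_months <- tapply(rep(1L, length(yr)), yr, sum)
  complete <- names(n_months)[n_months == 12L]
  dropped <- setdiff(names(n_months), complete)
  if (length(dropped) > 0L) {
    warning("dropping year(s) with incomplete monthly coverage: ",
            paste(dropped, collapse = ", "))
  }
  if (length(complete) == 0L) stop("no year has all 12 months of data")
  ann <- tapply(as.numeric(month_mean), yr, mean)[complete]
  annual_series(as.integer(complete), as.numeric(ann),
                name = "sea_ice_index", unit = "%")
}

#' Volume-weighted mean temperature of a basin
#'
#' Weights each depth level's temperature by the basin area at that depth
#' times the layer thickness, and normalises by total volume:
#' sum(T * A * dz) / sum(A * dz). This tracks total heat content better
#' than a plain depth average in basins that narrow with depth.
#'
#' @param temperature_c Numeric vector of temperatures per depth level.
#' @param area Basin area at each depth level (same length; any area unit).
#' @param dz Layer thickness per level (scalar or vector; default 1).
#' @return Volume-weighted mean temperature in the input unit.
#' @export
volume_weighted_temperature <- function(temperature_c, area, dz = 1) {
  stopifnot(length(temperature_c) == length(area))
  if (any(area < 0)) stop("areas must be non-negative")
  w <- area * dz
  vol <- sum(w)
  if (vol <= 0) stop("zero total volume: all areas (or thicknesses) are zero")
  sum(temperature_c * w) / vol
}

#' Remove the linear time trend from an annual series
#'
#' Replaces the series by its residuals from an OLS regression on year. The
#' output has mean zero and the operation is idempotent. Detrending before
#' correlating two series asks whether they co-vary beyond sharing a
#' long-term trend.
#'
#' @param series An [annual_series()] with at least 3 points.
#' @return An [annual_series()] of residuals.
#' @export
detrend <- function(series) {
  if (length(series) < 3L) stop("detrending needs at least 3 points")
  yr <- series_years(series)
  res <- stats::lm.fit(cbind(1, yr - yr[1L]), as.numeric(series))$residuals
  annual_series(yr, res,
                name = paste0(attr(series, "series_name") %||% "series",
                              " (detrended)"),
                unit = attr(series, "unit") %||% "")
}

#' Pearson correlation between two annual series
#'
#' Correlates the two series over their overlapping years
#' (pairwise-complete; gap years drop out), optionally detrending both
#' first. The 95% confidence interval comes from the Fisher z transform and
#' significance is judged by whether that interval excludes zero — the
#' decision rule used when correlations are displayed as CI whiskers — with
#' the t-test p value also reported.
#'
#' @param x,y [annual_series()] objects with at least `min_n` overlapping
#'   years.
#' @param detrended If `TRUE`, detrend both series (on the overlap) first.
#' @param min_n Minimum overlapping years (default 4).
#' @return A list of class `correlation_result`: `r`, `ci95`, `p`, `n`,
#'   `detrended`, `significant`, plus the series names.
#' @export
correlate <- function(x, y, detrended = FALSE, min_n = 4L) {
  yrs <- intersect(series_years(x), series_years(y))
  yrs <- yrs[!is.na(x[as.character(yrs)]) & !is.na(y[as.character(yrs)])]
  if (length(yrs) < min_n) {
    stop("need at least ", min_n, " overlapping years; have ", length(yrs))
  }
  xv <- annual_series(yrs, x[as.character(yrs)],
                      name = attr(x, "series_name") %||% "x")
  yv <- annual_series(yrs, y[as.character(yrs)],
                      name = attr(y, "series_name") %||% "y")
  if (detrended) {
    xv <- detrend(xv)
    yv <- detrend(yv)
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("zero variance in ", if (stats::sd(xv) == 0)
      attr(x, "series_name") else attr(y, "series_name"))
  }
  ct <- stats::cor.test(as.numeric(xv), as.numeric(yv), method = "pearson")
  ci <- as.numeric(ct$conf.int)
  out <- list(r = unname(ct$estimate), ci95 = ci, p = ct$p.value,
              n = length(yrs), detrended = detrended,
              significant = ci[1] > 0 || ci[2] < 0,
              x = attr(x, "series_name") %||% "x",
              y = attr(y, "series_name") %||% "y")
  class(out) <- "correlation_result"
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "Pearson correlation %s ~ %s%s: r = %.3f [%.3f, %.3f], p = %.3g, n = %d%s\n",
    x$x, x$y, if (x$detrended) " (detrended)" else "",
    x$r, x$ci95[1], x$ci95[2], x$p, x$n,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Correlation table over series pairs
#'
#' Runs [correlate()] for every combination of diet series, explanatory
#' series and detrending flag.
#'
#' @param diet Named list of [annual_series()] (responses).
#' @param env Named list of [annual_series()] (explanatory variables).
#' @param detrended Logical vector of detrending settings to apply
#'   (default both raw and detrended).
#' @return Data frame: `x`, `y`, `detrended`, `r`, `ci_lo`, `ci_hi`, `p`,
#'   `n`, `significant`.
#' @export
correlation_table <- function(diet, env, detrended = c(FALSE, TRUE)) {
  rows <- list()
  for (dn in names(diet)) for (en in names(env)) for (dt in detrended) {
    res <- tryCatch(correlate(diet[[dn]], env[[en]], detrended = dt),
                    error = function(e) NULL)
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      x = dn, y = en, detrended = dt, r = res$r,
      ci_lo = res$ci95[1], ci_hi = res$ci95[2], p = res$p, n = res$n,
      significant = res$significant, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear trend regression of an annual series
#'
#' OLS of value on year, with the year centred at the first observed year so
#' the intercept is the fitted level at the series start.
#'
#' @param series An [annual_series()] with at least 3 points.
#' @return A list: `slope` (per year), `intercept`, `slope_se`, `F`, `p`,
#'   `r_squared`, `n`, `first_year`. A constant series returns slope 0 with
#'   `F` and `p` as `NA`.
#' @export
trend_regression <- function(series) {
  if (length(series) < 3L) stop("trend regression needs at least 3 points")
  yr <- series_years(series)
  y <- as.numeric(series)
  X <- cbind(1, yr - yr[1L])
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  df_res <- n - 2L
  sigma2 <- rss / df_res
  se_slope <- sqrt(chol2inv(chol(crossprod(X)))[2L, 2L] * sigma2)
  if (tss > 0 && rss < tss) {
    Fstat <- (tss - rss) / max(sigma2, .Machine$double.eps)
    pval <- if (sigma2 > 0) stats::pf(Fstat, 1, df_res, lower.tail = FALSE)
      else 0
    r2 <- 1 - rss / tss
  } else {
    Fstat <- NA_real_; pval <- NA_real_
    r2 <- if (tss == 0) NA_real_ else 0
  }
  list(slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       slope_se = se_slope, F = Fstat, p = pval, r_squared = r2,
       n = n, first_year = yr[1L])
}
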