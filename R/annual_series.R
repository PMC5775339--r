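#' Construct an annual series
#'
#' A named numeric vector keyed by calendar year, the common currency of the
#' regime, trend and correlation machinery. Missing years are simply absent;
#' correlations use pairwise-complete years.
#'
#' @param years Integer years (unique).
#' @param values Numeric values, same length as `years`.
#' @param name Series name (used in printed output and correlation tables).
#' @param unit Measurement unit, for documentation only (e.g. `"%"`,
#'   `"degC"`, `"g"`).
#' @return Numeric vector of class `annual_series`, sorted by year.
#' @export
annual_series <- function(years, values, name = "series", unit = "") {
  years <- as.integer(years)
  stopifnot(length(years) == length(values))
  if (anyDuplicated(years)) stop("duplicated years in annual series")
  ord <- order(years)
  out <- as.numeric(values)[ord]
  names(out) <- years[ord]
  attr(out, "series_name") <- name
  attr(out, "unit") <- unit
  class(out) <- "annual_series"
  out
}

#' Years of an annual series
#' @param x An `annual_series`.
#' @return Integer vector of years.
#' @export
series_years <- function(x) as.integer(names(x))

#' @export
print.annual_series <- function(x, ...) {
  cat("Annual series '", attr(x, "series_name"), "'",
      if (nzchar(attr(x, "unit") %||% "")) paste0(" [", attr(x, "unit"), "]"),
      ": ", length(x), " years\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip class/attrs for arithmetic
as_plain <- function(x) stats::setNames(as.numeric(x), names(x))
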