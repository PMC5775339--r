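make_daily_ice <- function(year, monthly_pct) {
  dates <- seq(as.Date(paste0(year, "-01-01")),
               as.Date(paste0(year, "-12-31")), by = "day")
  pct <- monthly_pct[as.integer(format(dates, "%m"))]
  data.frame(date = rep(dates, each = 4),
             block_id = rep(1:4, length(dates)),
             concentration_pct = rep(pct, each = 4))
}

test_that("the sea-ice index averages days, then months, then the year", {
  expect_equal(as.numeric(sea_ice_index(make_daily_ice(2001, rep(100, 12)))),
               100)
  expect_equal(as.numeric(
    sea_ice_index(make_daily_ice(2001, c(rep(40, 6), rep(0, 6))))), 20)
  # month-first averaging: Jan (31 d) at 100, Feb (28 d) at 0, rest at 50
  # gives (100 + 0 + 10*50)/12 = 50, not the pooled-day 50.41
  ix <- sea_ice_index(make_daily_ice(2001, c(100, 0, rep(50, 10))))
  expect_equal(as.numeric(ix), 50)
})

test_that("bad or incomplete ice input is refused or dropped", {
  d <- make_daily_ice(2001, rep(50, 12))
  d$concentration_pct[1] <- 120
  expect_error(sea_ice_index(d), "\\[0, 100\\]")
  partial <- make_daily_ice(2001, rep(50, 12))
  partial <- partial[format(as.Date(partial$date), "%m") != "06", ]
  expect_error(expect_warning(sea_ice_index(partial), "incomplete"),
               "no year")
})

test_that("volume weighting follows the area-by-thickness formula", {
  expect_equal(volume_weighted_temperature(c(3, 3, 3), c(5, 4, 1)), 3)
  expect_equal(volume_weighted_temperature(c(2, 4), c(1, 1)), 3)
  # volumes 3:1 at 4 and 0 degrees -> (3*4 + 1*0)/4 = 3
  expect_equal(volume_weighted_temperature(c(4, 0), c(3, 1)), 3)
  # thickness weighting is equivalent to area scaling
  expect_equal(volume_weighted_temperature(c(4, 0), c(1, 1), dz = c(3, 1)), 3)
  expect_error(volume_weighted_temperature(c(1, 2), c(0, 0)), "zero total")
})

test_that("detrending removes exactly the OLS line and is idempotent", {
  yrs <- 2001:2010
  lin <- annual_series(yrs, 5 + 2 * (yrs - 2001), "lin")
  expect_equal(as.numeric(detrend(lin)), rep(0, 10))
  expect_equal(as.numeric(detrend(annual_series(yrs, rep(4, 10), "c"))),
               rep(0, 10))
  # a pattern orthogonal to (1, year) survives detrending unchanged
  pat <- c(1, -1, -1, 1)
  s <- annual_series(2001:2004, 10 + 3 * (0:3) + pat, "pat")
  expect_equal(as.numeric(detrend(s)), pat)
  set.seed(2); noisy <- annual_series(yrs, rnorm(10) + yrs, "n")
  d1 <- detrend(noisy)
  expect_equal(mean(d1), 0)
  expect_equal(as.numeric(detrend(d1)), as.numeric(d1))
  expect_error(detrend(annual_series(2001:2002, c(1, 2), "short")),
               "at least 3")
})

test_that("correlation is symmetric, bounded and CI-consistent", {
  set.seed(5)
  x <- annual_series(1997:2016, rnorm(20) + 0.3 * (0:19), "x")
  y <- annual_series(1997:2016, rnorm(20) + 0.2 * (0:19), "y")
  cxy <- correlate(x, y); cyx <- correlate(y, x)
  expect_equal(cxy$r, cyx$r)
  expect_true(cxy$r >= -1 && cxy$r <= 1)
  expect_true(cxy$ci95[1] <= cxy$r && cxy$r <= cxy$ci95[2])
  # perfect linear relation
  lin <- correlate(annual_series(1997:2016, 0:19, "a"),
                   annual_series(1997:2016, 2 * (0:19) + 1, "b"))
  expect_equal(lin$r, 1)
  expect_error(correlate(x, annual_series(1997:2016, rep(1, 20), "flat")),
               "zero variance")
  expect_error(correlate(x, annual_series(1901:1903, 1:3, "off")),
               "overlapping years")
})

test_that("correlation uses pairwise-complete overlapping years only", {
  x <- annual_series(c(1997:1998, 2004:2016), rnorm(15) + 1:15, "gappy")
  y <- annual_series(1997:2016, rnorm(20) + 1:20, "full")
  res <- correlate(x, y)
  expect_equal(res$n, 15L)
})

test_that("a series equals its trend plus detrended residuals", {
  set.seed(9)
  s <- annual_series(1997:2016, rnorm(20, sd = 2) + 0.5 * (0:19), "s")
  tr <- trend_regression(s)
  recon <- tr$intercept + tr$slope * (series_years(s) - tr$first_year) +
    as.numeric(detrend(s))
  expect_equal(recon, as.numeric(s))
  rebuilt <- annual_series(series_years(s), recon, "rebuilt")
  expect_equal(correlate(s, rebuilt)$r, 1)
})

test_that("trend regression reports slope, F and R-squared correctly", {
  yrs <- 1997:2016
  noiseless <- annual_series(yrs, 25.0 - 0.7 * (yrs - 1997), "ww")
  tr <- trend_regression(noiseless)
  expect_equal(tr$slope, -0.7)
  expect_equal(tr$intercept, 25.0)
  expect_equal(tr$r_squared, 1)
  flat <- trend_regression(annual_series(yrs, rep(2, 20), "flat"))
  expect_equal(flat$slope, 0)
  expect_true(is.na(flat$F))
  expect_error(trend_regression(annual_series(2001:2002, 1:2, "short")),
               "at least 3")
})

test_that("correlation table crosses series and detrending settings", {
  set.seed(4)
  diet <- list(a = annual_series(1997:2016, rnorm(20) + 0:19, "a"))
  env <- list(ice = annual_series(1997:2016, rnorm(20) - 0:19, "ice"))
  tab <- correlation_table(diet, env)
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$detrended, c(TRUE, FALSE))
  expect_true(all(tab$ci_lo <= tab$r & tab$r <= tab$ci_hi))
})
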