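step_series <- function() {
  annual_series(2001:2006, c(10, 10, 10, 50, 50, 50), "step")
}

test_that("a noiseless step is fitted exactly by the constant change-point", {
  fit <- fit_form(step_series(), "constant_changepoint", changepoint = 2003)
  expect_equal(fit$coefficients$estimate, c(10, 50))
  expect_equal(fit$rss, 0)
  expect_equal(fit$coefficients$term,
               c("Intercept 2001-2003", "Intercept 2004-2006"))
})

test_that("noiseless lines recover their parameters to machine precision", {
  yrs <- 2001:2010
  lin <- annual_series(yrs, 3 + 2 * (yrs - 2001), "line")
  fit <- fit_form(lin, "linear")
  expect_equal(fit$coefficients$estimate, c(3, 2))
  expect_equal(fit$rss, 0, tolerance = 1e-20)

  # two different lines joined at a change-point
  y <- ifelse(yrs <= 2005, 1 + 2 * (yrs - 2001), 40 - 3 * (yrs - 2001))
  fit2 <- fit_form(annual_series(yrs, y, "kink"),
                   "linear_interaction_changepoint", changepoint = 2005)
  est <- fit2$coefficients$estimate
  expect_equal(est[c(1, 3)], c(1, 2))   # pre intercept, slope
  expect_equal(est[c(2, 4)], c(40, -3)) # post intercept, slope
  expect_equal(fit2$rss, 0, tolerance = 1e-18)
})

test_that("segments shorter than min_segment are refused", {
  expect_error(fit_form(step_series(), "constant_changepoint",
                        changepoint = 2002), "min_segment")
})

test_that("the change-point scan locates a step exactly", {
  best <- scan_changepoints(step_series(), "constant_changepoint")
  expect_equal(best$changepoint, 2003L)
  prof <- attr(best, "profile")
  expect_true(is.data.frame(prof) && all(c("changepoint", "aicc") %in%
                                           names(prof)))
  expect_error(scan_changepoints(step_series(), "constant_changepoint",
                                 window = c(1800, 1900)), "admissible")
  expect_error(scan_changepoints(step_series(), "linear"), "no changepoint")
})

test_that("model selection recovers the generating form on noiseless data", {
  yrs <- 2001:2012
  cases <- list(
    list(y = rep(7, 12), form = "constant"),
    list(y = 5 - 0.7 * (yrs - 2001), form = "linear"),
    list(y = ifelse(yrs <= 2006, 10, 50), form = "constant_changepoint"),
    list(y = ifelse(yrs <= 2006, 1 + 2 * (yrs - 2001),
                    60 - 3 * (yrs - 2001)),
         form = "linear_interaction_changepoint"))
  for (case in cases) {
    win <- select_model(annual_series(yrs, case$y, case$form))
    expect_equal(win$form, case$form)
    expect_equal(win$rss, 0, tolerance = 1e-12)
  }
})

test_that("selection penalises parameters at equal fit quality", {
  # on a pure line every change-point form also interpolates; the linear
  # form must win on parsimony, never a change-point form
  yrs <- 2001:2012
  win <- select_model(annual_series(yrs, 1 + 2 * (yrs - 2001), "line"))
  expect_equal(win$form, "linear")
  rk <- attr(win, "ranking")
  expect_true(all(c("form", "aicc", "delta_aicc") %in% names(rk)))
  # every other interpolating form carries more parameters than the winner
  perfect <- rk[rk$rss < 1e-12 & rk$form != "linear", ]
  expect_true(all(perfect$n_params > win$n_params))
})

test_that("AICc improves with residual SS at fixed parameter count", {
  yrs <- 2001:2015
  base <- 2 * (yrs - 2001)
  noisy1 <- annual_series(yrs, base + c(1, -1)[1 + (yrs %% 2)], "n1")
  noisy2 <- annual_series(yrs, base + 5 * c(1, -1)[1 + (yrs %% 2)], "n2")
  f1 <- fit_form(noisy1, "linear")
  f2 <- fit_form(noisy2, "linear")
  expect_lt(f1$rss, f2$rss)
  expect_lt(f1$aicc, f2$aicc)
})

test_that("regime labels follow the last-year-of-previous-regime rule", {
  fit <- fit_form(annual_series(1982:2016, rnorm(35) +
                                  ifelse(1982:2016 <= 2006, 78, 37), "fo"),
                  "constant_changepoint", changepoint = 2006)
  expect_equal(fit$coefficients$term,
               c("Intercept 1982-2006", "Intercept 2007-2016"))
})

test_that("the explanatory window constrains admissible change-points", {
  yrs <- 1982:2016
  y <- ifelse(yrs <= 1990, 100, 10) + rnorm(length(yrs), sd = 0.1)
  s <- annual_series(yrs, y, "early_step")
  free <- scan_changepoints(s, "constant_changepoint")
  expect_equal(free$changepoint, 1990L)
  late <- scan_changepoints(s, "constant_changepoint",
                            window = c(1996, Inf))
  expect_gte(late$changepoint, 1996L)
})

test_that("regime_report flattens a fit into the standard table layout", {
  rep <- regime_report(fit_form(step_series(), "constant_changepoint",
                                changepoint = 2003), variable = "toy")
  expect_equal(names(rep), c("variable", "type", "term", "estimate", "df",
                             "stat", "p", "changepoint"))
  expect_equal(rep$type[1], "Constant change-point")
  expect_equal(rep$term[1], "(model)")
  expect_equal(nrow(rep), 3L)
})
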