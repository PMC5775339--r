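#' @title Change-point regime models for annual series
#' @description
#' An annual series is described by one of five candidate model forms, all
#' ordinary least squares:
#'
#' * `constant` — a single mean;
#' * `linear` — a single trend line;
#' * `constant_changepoint` — one mean per regime (a step);
#' * `linear_changepoint` — a shared slope with a regime-specific intercept
#'   shift;
#' * `linear_interaction_changepoint` — a separate intercept and slope per
#'   regime.
#'
#' A change-point is reported as the *last year of the previous regime*:
#' a shift between year y and y+1 is the change-point y, and the regimes
#' render as "start–y" and "(y+1)–end". Candidate change-points are scanned
#' exhaustively and forms are ranked by AICc, the small-sample corrected
#' information criterion — appropriate because these series rarely exceed
#' ~20 points. When two forms fit indistinguishably (Delta-AICc < 0.01, as
#' happens for exactly noiseless data), the form with fewer parameters wins.
#' @name regime-models
NULL

#' Candidate model forms for regime analysis
#' @return Character vector of the five form names.
#' @export
regime_forms <- function() {
  c("constant", "linear", "constant_changepoint", "linear_changepoint",
    "linear_interaction_changepoint")
}

form_has_changepoint <- function(form) {
  form %in% c("constant_changepoint", "linear_changepoint",
              "linear_interaction_changepoint")
}

# Design matrix for a form. Years are centred at the first observed year so
# intercepts are interpretable as the level at the series start.
regime_design <- function(years, form, changepoint, origin_year) {
  yr <- years - origin_year
  if (form_has_changepoint(form)) {
    post <- years > changepoint
    pre <- !post
    lab1 <- paste0("Intercept ", min(years), "-", changepoint)
    lab2 <- paste0("Intercept ", changepoint + 1L, "-", max(years))
  }
  switch(form,
    constant = matrix(1, length(years), 1L,
                      dimnames = list(NULL, "Intercept")),
    linear = cbind(Intercept = rep(1, length(years)), Slope = yr),
    constant_changepoint = {
      m <- cbind(as.numeric(pre), as.numeric(post))
      colnames(m) <- c(lab1, lab2)
      m
    },
    linear_changepoint = {
      m <- cbind(as.numeric(pre), as.numeric(post), yr)
      colnames(m) <- c(lab1, lab2, "Slope")
      m
    },
    linear_interaction_changepoint = {
      m <- cbind(as.numeric(pre), as.numeric(post), yr * pre, yr * post)
      colnames(m) <- c(lab1, lab2,
                       paste0("Slope ", min(years), "-", changepoint),
                       paste0("Slope ", changepoint + 1L, "-", max(years)))
      m
    },
    stop("unknown model form: ", form))
}

# AICc for a Gaussian OLS fit; k counts coefficients plus the variance.
# Residual sums of squares are floored at a scale-relative epsilon so that
# exactly-interpolating fits remain comparable (otherwise the log-likelihood
# diverges and parameter-count penalties could never break ties).
aicc_ols <- function(rss, n, p) {
  k <- p + 1
  if (n - k - 1 <= 0) return(Inf)
  floor_rss <- max(rss, n * 1e-12)
  n * log(floor_rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit one candidate model form to an annual series
#'
#' @param series An [annual_series()].
#' @param form One of [regime_forms()].
#' @param changepoint Change-point year (last year of the previous regime);
#'   required for change-point forms, ignored otherwise.
#' @param min_segment Minimum observed years per regime (default 3, so each
#'   regime of a linear form keeps at least one residual degree of freedom).
#' @return A `regime_fit`: coefficients with standard errors, t and p values,
#'   residual degrees of freedom, whole-model F against the constant model,
#'   residual sum of squares, and the AICc selection score.
#' @export
fit_form <- function(series, form = regime_forms(), changepoint = NULL,
                     min_segment = 3L) {
  form <- match.arg(form)
  years <- series_years(series)
  y <- as.numeric(series)
  n <- length(y)
  if (form_has_changepoint(form)) {
    if (is.null(changepoint)) stop("form '", form, "' needs a changepoint year")
    n_pre <- sum(years <= changepoint)
    n_post <- n - n_pre
    if (n_pre < min_segment || n_post < min_segment) {
      stop("segment shorter than min_segment (", min_segment, ") at ",
           "changepoint ", changepoint)
    }
  } else {
    changepoint <- NULL
  }
  X <- regime_design(years, form, changepoint, origin_year = min(years))
  p <- ncol(X)
  if (n <= p) stop("too few points (", n, ") for form '", form, "'")
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  df_res <- n - p
  sigma2 <- rss / df_res
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(diag(XtX_inv) * sigma2, 0))
  tval <- ifelse(se > 0, fit$coefficients / se, NA_real_)
  pval <- 2 * stats::pt(-abs(tval), df_res)
  tss <- sum((y - mean(y))^2)
  if (p > 1L && rss > 0 && tss > rss) {
    Fstat <- ((tss - rss) / (p - 1)) / sigma2
    Fp <- stats::pf(Fstat, p - 1, df_res, lower.tail = FALSE)
  } else if (p > 1L && tss > 0 && rss == 0) {
    Fstat <- Inf; Fp <- 0
  } else {
    Fstat <- NA_real_; Fp <- NA_real_
  }
  out <- list(
    form = form,
    changepoint = changepoint,
    coefficients = data.frame(
      term = colnames(X),
      estimate = unname(fit$coefficients),
      se = unname(se),
      t = unname(tval),
      p = unname(pval),
      stringsAsFactors = FALSE),
    n = n, n_params = p, df_residual = df_res,
    rss = rss, F = Fstat, F_p = Fp,
    aicc = aicc_ols(rss, n, p),
    fitted = stats::setNames(fit$fitted.values, years),
    years = years,
    series_name = attr(series, "series_name") %||% "series")
  class(out) <- "regime_fit"
  out
}

#' @export
print.regime_fit <- function(x, ...) {
  lab <- if (form_has_changepoint(x$form)) {
    paste0(x$form, " (regimes ", min(x$years), "-", x$changepoint, " / ",
           x$changepoint + 1L, "-", max(x$years), ")")
  } else x$form
  cat("Regime model for '", x$series_name, "': ", lab, "\n", sep = "")
  cat(sprintf("  n = %d, residual df = %d, RSS = %.4g, AICc = %.2f\n",
              x$n, x$df_residual, x$rss, x$aicc))
  if (!is.na(x$F)) {
    cat(sprintf("  model F = %.1f, p = %.3g\n", x$F, x$F_p))
  }
  co <- x$coefficients
  co$estimate <- signif(co$estimate, 4)
  co$se <- signif(co$se, 3)
  co$t <- round(co$t, 1)
  co$p <- signif(co$p, 3)
  print(co, row.names = FALSE)
  invisible(x)
}

#' Scan candidate change-point years for one form
#'
#' Fits the form at every admissible change-point year (each regime keeping
#' at least `min_segment` observed years, optionally restricted to a window)
#' and returns the AICc-best fit together with the full score profile.
#'
#' @inheritParams fit_form
#' @param window Optional `c(min, max)` restricting admissible change-point
#'   years (the change-point is the last year of the previous regime; to
#'   exclude shifts before 1997 use `window = c(1996, Inf)`).
#' @return The best `regime_fit`; attribute `profile` is a data frame of
#'   (changepoint, rss, aicc) across candidates.
#' @export
scan_changepoints <- function(series, form = regime_forms(), window = NULL,
                              min_segment = 3L) {
  form <- match.arg(form)
  if (!form_has_changepoint(form)) {
    stop("form '", form, "' has no changepoint to scan")
  }
  years <- series_years(series)
  n <- length(years)
  idx <- seq_len(n)
  cand <- years[idx >= min_segment & idx <= n - min_segment]
  if (!is.null(window)) cand <- cand[cand >= window[1] & cand <= window[2]]
  if (length(cand) == 0L) {
    stop("no admissible changepoint years (series too short or window empty)")
  }
  fits <- lapply(cand, function(cp) {
    fit_form(series, form, changepoint = cp, min_segment = min_segment)
  })
  scores <- vapply(fits, function(f) f$aicc, 0)
  best <- fits[[which.min(scores)]]
  attr(best, "profile") <- data.frame(
    changepoint = cand,
    rss = vapply(fits, function(f) f$rss, 0),
    aicc = scores)
  best
}

#' Select the best regime model for an annual series
#'
#' Fits every requested form — scanning change-points where the form has one
#' — and ranks them by AICc. Near-ties (Delta-AICc below `tie_delta`) go to
#' the form with fewer parameters, so noiseless data generated from a simple
#' form is never over-fitted by a richer one.
#'
#' @inheritParams scan_changepoints
#' @param forms Character vector of candidate forms (default: all five).
#' @return The winning `regime_fit`; attribute `ranking` is a data frame of
#'   all candidates sorted by AICc (form, changepoint, n_params, rss, aicc,
#'   delta_aicc).
#' @export
select_model <- function(series, forms = regime_forms(), window = NULL,
                         min_segment = 3L, tie_delta = 0.01) {
  forms <- match.arg(forms, several.ok = TRUE)
  if (length(forms) < 2L) stop("need at least two candidate forms")
  fits <- list()
  for (form in forms) {
    f <- if (form_has_changepoint(form)) {
      tryCatch(scan_changepoints(series, form, window = window,
                                 min_segment = min_segment),
               error = function(e) NULL)
    } else {
      tryCatch(fit_form(series, form, min_segment = min_segment),
               error = function(e) NULL)
    }
    if (!is.null(f)) fits[[form]] <- f
  }
  if (length(fits) == 0L) stop("no candidate form could be fitted")
  ranking <- data.frame(
    form = vapply(fits, function(f) f$form, ""),
    changepoint = vapply(fits, function(f) {
      if (is.null(f$changepoint)) NA_integer_ else f$changepoint
    }, 0L),
    n_params = vapply(fits, function(f) f$n_params, 0L),
    rss = vapply(fits, function(f) f$rss, 0),
    aicc = vapply(fits, function(f) f$aicc, 0),
    stringsAsFactors = FALSE)
  ranking <- ranking[order(ranking$aicc, ranking$n_params), , drop = FALSE]
  ranking$delta_aicc <- ranking$aicc - ranking$aicc[1L]
  # tie-break: among near-equal scores prefer the most parsimonious form
  near <- which(ranking$delta_aicc < tie_delta)
  pick <- near[which.min(ranking$n_params[near])]
  winner <- fits[[ranking$form[pick]]]
  rownames(ranking) <- NULL
  attr(winner, "ranking") <- ranking
  winner
}

#' Flatten a regime fit into a report table
#'
#' One row per model term plus a whole-model row, mirroring the usual
#' reporting layout for change-point model tables (Type, Term, Est., Df,
#' Stat., P) where "Stat." is t for terms and F for the whole model.
#'
#' @param fit A `regime_fit`.
#' @param variable Optional variable label for the first column.
#' @return A data frame.
#' @export
regime_report <- function(fit, variable = fit$series_name) {
  stopifnot(inherits(fit, "regime_fit"))
  type <- c(constant = "Constant", linear = "Linear",
            constant_changepoint = "Constant change-point",
            linear_changepoint = "Linear change-point",
            linear_interaction_changepoint =
              "Linear interaction change-point")[[fit$form]]
  model_row <- data.frame(
    variable = variable, type = type, term = "(model)",
    estimate = NA_real_, df = fit$df_residual,
    stat = fit$F, p = fit$F_p,
    changepoint = if (is.null(fit$changepoint)) NA_integer_ else
      fit$changepoint,
    stringsAsFactors = FALSE)
  term_rows <- data.frame(
    variable = variable, type = type, term = fit$coefficients$term,
    estimate = fit$coefficients$estimate, df = fit$df_residual,
    stat = fit$coefficients$t, p = fit$coefficients$p,
    changepoint = if (is.null(fit$changepoint)) NA_integer_ else
      fit$changepoint,
    stringsAsFactors = FALSE)
  rbind(model_row, term_rows)
}
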