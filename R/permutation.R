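#' Two-sample permutation test on the difference of means
#'
#' Tests whether two groups of per-sample masses share a distribution, using
#' the difference of group means as the statistic and a two-sided null.
#' Small problems are enumerated exactly (every reassignment of the pooled
#' values into groups of the observed sizes); larger ones are approximated
#' by Monte Carlo with the standard +1 correction, which keeps the test
#' valid at any permutation count.
#'
#' @param a,b Numeric vectors (e.g. per-sample wet masses of two prey
#'   origins); both must be non-empty.
#' @param n_perm Monte-Carlo permutation count (default 9999).
#' @param seed Optional integer seed; fixed seed gives identical results.
#' @param mode `"auto"` switches to exact enumeration when the number of
#'   assignments `choose(nA+nB, nA)` is at most `exact_limit`; `"exact"` and
#'   `"monte_carlo"` force a mode.
#' @param exact_limit Enumeration ceiling for `mode = "auto"`.
#' @return A list of class `permutation_result`: `statistic` (mean(a) -
#'   mean(b)), `p` (two-sided), `mode`, `n_perm` (enumeration count in exact
#'   mode), `n_a`, `n_b`, `seed`.
#' @export
permutation_test <- function(a, b, n_perm = 9999L, seed = NULL,
                             mode = c("auto", "exact", "monte_carlo"),
                             exact_limit = 10000) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  pooled <- c(a, b)
  obs <- mean(a) - mean(b)
  tol <- 1e-8 * (max(abs(pooled)) + 1)
  if (mode == "auto") {
    mode <- if (choose(n, n_a) <= exact_limit) "exact" else "monte_carlo"
  }
  tot <- sum(pooled)
  # statistic from the group-a sum: T = sA/nA - (tot - sA)/nB
  stat_from_sum <- function(s_a) s_a / n_a - (tot - s_a) / n_b
  if (mode == "exact") {
    sums <- utils::combn(pooled, n_a, sum)
    stats_all <- stat_from_sum(sums)
    p <- mean(abs(stats_all) >= abs(obs) - tol)
    n_used <- length(sums)
  } else {
    if (!is.null(seed)) set.seed(seed)
    sums <- vapply(seq_len(n_perm),
                   function(i) sum(pooled[sample.int(n, n_a)]), 0)
    stats_all <- stat_from_sum(sums)
    p <- (sum(abs(stats_all) >= abs(obs) - tol) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  out <- list(statistic = obs, p = p, mode = mode, n_perm = n_used,
              n_a = n_a, n_b = n_b, seed = seed)
  class(out) <- "permutation_result"
  out
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Two-sample permutation test (", x$mode, ", ",
      if (x$mode == "exact") paste0(x$n_perm, " assignments")
      else paste0(x$n_perm, " permutations"),
      ")\n", sep = "")
  cat(sprintf("  mean difference = %.3f g, two-sided p = %.4g (n = %d, %d)\n",
              x$statistic, x$p, x$n_a, x$n_b))
  invisible(x)
}

#' Annual Arctic-vs-Atlantic (or any origin pair) mass comparison
#'
#' For every mass-based year, compares the per-sample wet masses of two prey
#' origin classes with a two-sample permutation test. Each sample
#' contributes one value per origin — zero when it contains none of that
#' origin's prey — so both vectors have the year's sample count as length.
#' Years without mass data are skipped and listed in the `skipped_years`
#' attribute.
#'
#' @param x A `diet_samples` object.
#' @param origins Character pair of origin classes (default Arctic vs
#'   Atlantic).
#' @param n_perm,seed,mode Passed to [permutation_test()]; each year gets a
#'   seed derived from `seed` so the whole table is reproducible.
#' @param alpha Significance level for the per-year flags (no multiplicity
#'   correction by default, matching per-year reporting conventions).
#' @param holm If `TRUE`, add a Holm-adjusted significance column.
#' @param include_zeros If `TRUE` (default) every sample contributes to both
#'   vectors; if `FALSE` only samples containing the respective origin do.
#' @param catalog A `taxon_catalog`.
#' @return Data frame: `year`, `mean_a_g`, `mean_b_g`, `diff_g`, `p`,
#'   `significant`, `dominant` (origin with the larger mean in flagged
#'   years), `n_samples`, `mode`.
#' @export
annual_group_comparison <- function(x, origins = c("arctic", "atlantic"),
                                    n_perm = 9999L, seed = NULL,
                                    mode = "auto", alpha = 0.05,
                                    holm = FALSE, include_zeros = TRUE,
                                    catalog = default_catalog()) {
  stopifnot(inherits(x, "diet_samples"), length(origins) == 2L)
  mb <- subset_samples(x, mass_based = TRUE)
  skipped <- setdiff(x$years, mb$years)
  if (length(skipped) > 0L) {
    warning("skipping years without mass data: ",
            paste(skipped, collapse = ", "))
  }
  rows <- lapply(seq_along(mb$years), function(i) {
    yr <- mb$years[i]
    sc <- subset_samples(mb, years = yr)
    va <- origin_mass(sc, origins[1], catalog)
    vb <- origin_mass(sc, origins[2], catalog)
    if (!include_zeros) {
      va <- va[va > 0]
      vb <- vb[vb > 0]
    }
    if (length(va) == 0L || length(vb) == 0L) {
      return(data.frame(year = yr, mean_a_g = mean(va), mean_b_g = mean(vb),
                        diff_g = NA_real_, p = NA_real_, significant = FALSE,
                        dominant = NA_character_, n_samples = sc$n_samples,
                        mode = NA_character_, stringsAsFactors = FALSE))
    }
    yr_seed <- if (is.null(seed)) NULL else (seed + i) %% 2147483647L
    res <- permutation_test(va, vb, n_perm = n_perm, seed = yr_seed,
                            mode = mode)
    data.frame(year = yr, mean_a_g = mean(va), mean_b_g = mean(vb),
               diff_g = res$statistic, p = res$p,
               significant = res$p < alpha,
               dominant = ifelse(res$p < alpha,
                                 origins[(res$statistic < 0) + 1L],
                                 NA_character_),
               n_samples = sc$n_samples, mode = res$mode,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_a_g"] <- paste0("mean_", origins[1], "_g")
  names(out)[names(out) == "mean_b_g"] <- paste0("mean_", origins[2], "_g")
  if (holm) {
    adj <- stats::p.adjust(out$p, method = "holm")
    out$p_holm <- adj
    out$significant_holm <- !is.na(adj) & adj < alpha
  }
  attr(out, "skipped_years") <- skipped
  attr(out, "alpha") <- alpha
  out
}
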