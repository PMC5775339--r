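#' @title Diet composition indices
#' @description
#' Four metrics summarise how much a prey category contributes to the diet:
#'
#' * **FO** (frequency of occurrence, %): share of samples containing the
#'   category. Presence suffices, so FO spans binary-era and mass-based data.
#' * **WW** (average wet weight, g): mean category mass per sample, zeros
#'   included — a proxy of energetic importance.
#' * **MM** (average meal mass, g): mean category mass over only the samples
#'   where the category is present.
#' * **AP** (average mass percentage, %): mean over samples of the category's
#'   share of the sample's total mass; gives each sample equal weight and
#'   damps outliers.
#'
#' The three mass metrics are linked by the identity `WW = MM * N / n`, with
#' `N` the number of samples containing the category and `n` the number of
#' samples in scope.
#' @name diet-indices
NULL

# Per-sample presence of a category (taxon key, origin class, or group).
category_presence <- function(x, category, catalog = default_catalog()) {
  stopifnot(inherits(x, "diet_samples"))
  it <- x$items
  hit <- category_items(it, category, catalog)
  pres <- stats::setNames(logical(x$n_samples), x$samples$sample_id)
  if (any(hit)) pres[unique(it$sample_id[hit])] <- TRUE
  pres
}

# Per-sample mass of a category; requires mass-based samples.
category_mass <- function(x, category, catalog = default_catalog()) {
  stopifnot(inherits(x, "diet_samples"))
  if (any(x$samples$presence_only)) {
    stop("mass-based metric requested on presence-only samples (subset first)")
  }
  it <- x$items
  hit <- category_items(it, category, catalog)
  out <- stats::setNames(numeric(x$n_samples), x$samples$sample_id)
  if (any(hit)) {
    s <- tapply(it$wet_mass_g[hit], it$sample_id[hit], sum, na.rm = TRUE)
    out[names(s)] <- as.numeric(s)
  }
  out
}

# Which item rows belong to a category. A category is either a taxon key,
# an origin class, or a group/subgroup label from the catalog.
category_items <- function(items, category, catalog) {
  if (nrow(items) == 0L) return(logical(0))
  if (category %in% catalog$taxon) {
    items$taxon == category
  } else if (category %in% origin_classes()) {
    origin_of(items$taxon, catalog) == category
  } else if (category %in% c(catalog$group, catalog$subgroup)) {
    idx <- match(items$taxon, catalog$taxon)
    grp <- catalog$group[idx]
    sub <- catalog$subgroup[idx]
    (!is.na(grp) & grp == category) | (!is.na(sub) & sub == category)
  } else {
    stop("unknown category: ", category)
  }
}

scope_table <- function(x, years, mass_based) {
  out <- subset_samples(x, years = years, mass_based = mass_based)
  if (out$n_samples == 0L) {
    stop("no ", if (mass_based) "mass-based " else "", "samples in scope")
  }
  out
}

#' Frequency of occurrence of a prey category
#'
#' @param x A `diet_samples` object.
#' @param category Taxon key, origin class, or catalog group/subgroup.
#' @param years Optional year subset; default pools all years.
#' @param catalog A `taxon_catalog`.
#' @return FO in percent (0-100).
#' @export
frequency_of_occurrence <- function(x, category, years = NULL,
                                    catalog = default_catalog()) {
  sc <- scope_table(x, years, mass_based = FALSE)
  100 * mean(category_presence(sc, category, catalog))
}

#' Average wet weight (WW) of a prey category
#'
#' Mean category mass over all mass-based samples in scope, zeros included.
#'
#' @inheritParams frequency_of_occurrence
#' @return List with `mean` (g), `sem` (g; `NA` for a single sample) and
#'   `n` (samples in scope).
#' @export
average_wet_weight <- function(x, category, years = NULL,
                               catalog = default_catalog()) {
  sc <- scope_table(x, years, mass_based = TRUE)
  v <- category_mass(sc, category, catalog)
  list(mean = mean(v), sem = sem(v), n = length(v))
}

#' Average meal mass (MM) of a prey category
#'
#' Mean category mass over only the samples containing the category.
#'
#' @inheritParams frequency_of_occurrence
#' @return List with `mean` (g), `sem` (g) and `n_occ` (occurrences).
#' @export
average_meal_mass <- function(x, category, years = NULL,
                              catalog = default_catalog()) {
  sc <- scope_table(x, years, mass_based = TRUE)
  v <- category_mass(sc, category, catalog)
  pres <- category_presence(sc, category, catalog)
  if (!any(pres)) {
    stop("category '", category, "' does not occur in scope; ",
         "meal mass is undefined (not zero)")
  }
  v <- v[pres]
  list(mean = mean(v), sem = sem(v), n_occ = length(v))
}

#' Average mass percentage (AP) of a prey category
#'
#' Mean over samples of the category's percentage of the sample's total wet
#' mass. Samples whose total mass is zero contribute no defined fraction and
#' are excluded from the mean.
#'
#' @inheritParams frequency_of_occurrence
#' @return List with `mean` (%), `sem` (%) and `n` (samples with nonzero
#'   total mass).
#' @export
average_mass_percentage <- function(x, category, years = NULL,
                                    catalog = default_catalog()) {
  sc <- scope_table(x, years, mass_based = TRUE)
  tot <- total_mass(sc)
  keep <- tot > 0
  if (!any(keep)) stop("all samples in scope have zero total mass")
  v <- category_mass(sc, category, catalog)
  frac <- 100 * v[keep] / tot[keep]
  list(mean = mean(frac), sem = sem(frac), n = sum(keep))
}

sem <- function(v) {
  if (length(v) < 2L) return(NA_real_)
  stats::sd(v) / sqrt(length(v))
}

#' Full index table for a set of categories
#'
#' Applies all four diet metrics to every category, pooled or per year.
#' FO uses all samples in scope (binary-era included); WW, MM and AP use the
#' mass-based samples only. Categories never occurring in a scope get
#' `NA` meal mass rather than zero.
#'
#' @param x A `diet_samples` object.
#' @param categories Character vector of categories (taxa, origin classes or
#'   groups). Default: every taxon present plus the four named origin
#'   classes.
#' @param by_year If `TRUE`, one row per (category, year); otherwise pooled.
#' @param catalog A `taxon_catalog`.
#' @return Data frame with columns `category`, `year` (`NA` when pooled),
#'   `n_samples`, `fo_pct`, `n_occ`, `ww_g`, `ww_sem`, `mm_g`, `mm_sem`,
#'   `ap_pct`, `ap_sem`.
#' @export
index_table <- function(x, categories = NULL, by_year = FALSE,
                        catalog = default_catalog()) {
  stopifnot(inherits(x, "diet_samples"))
  if (is.null(categories)) {
    categories <- c(sort(unique(x$items$taxon)),
                    setdiff(origin_classes(), "unidentified"))
    categories <- categories[categories %in%
                               c(catalog$taxon, origin_classes())]
  }
  scopes <- if (by_year) as.list(x$years) else list(NULL)
  rows <- list()
  for (yrs in scopes) {
    sc_all <- subset_samples(x, years = yrs)
    sc_mass <- subset_samples(x, years = yrs, mass_based = TRUE)
    has_mass <- sc_mass$n_samples > 0L
    if (has_mass) tot <- total_mass(sc_mass)
    for (cat in categories) {
      pres <- category_presence(sc_all, cat, catalog)
      fo <- 100 * mean(pres)
      n_occ <- if (has_mass) {
        sum(category_presence(sc_mass, cat, catalog))
      } else 0L
      ww <- mm <- ap <- ww_se <- mm_se <- ap_se <- NA_real_
      if (has_mass) {
        v <- category_mass(sc_mass, cat, catalog)
        ww <- mean(v); ww_se <- sem(v)
        if (n_occ > 0L) {
          occ <- v[category_presence(sc_mass, cat, catalog)]
          mm <- mean(occ); mm_se <- sem(occ)
        }
        keep <- tot > 0
        if (any(keep)) {
          frac <- 100 * v[keep] / tot[keep]
          ap <- mean(frac); ap_se <- sem(frac)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat,
        year = if (is.null(yrs)) NA_integer_ else as.integer(yrs),
        n_samples = sc_all$n_samples,
        fo_pct = fo, n_occ = as.integer(n_occ),
        ww_g = ww, ww_sem = ww_se,
        mm_g = mm, mm_sem = mm_se,
        ap_pct = ap, ap_sem = ap_se,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annual frequency-of-occurrence series for a category
#'
#' Convenience bridge from a sample table to the annual-series machinery:
#' FO (%) per year for one category, e.g. the Arctic origin class.
#'
#' @inheritParams frequency_of_occurrence
#' @return An [annual_series()] in percent.
#' @export
fo_series <- function(x, category, catalog = default_catalog()) {
  stopifnot(inherits(x, "diet_samples"))
  vals <- vapply(x$years, function(y) {
    frequency_of_occurrence(x, category, years = y, catalog = catalog)
  }, 0)
  annual_series(x$years, vals, name = paste0("FO ", category), unit = "%")
}

#' Annual average-wet-weight series for a category
#'
#' WW (g) per mass-based year; binary-era years are skipped.
#'
#' @inheritParams frequency_of_occurrence
#' @return An [annual_series()] in grams.
#' @export
ww_series <- function(x, category, catalog = default_catalog()) {
  stopifnot(inherits(x, "diet_samples"))
  mb <- subset_samples(x, mass_based = TRUE)
  vals <- vapply(mb$years, function(y) {
    average_wet_weight(mb, category, years = y, catalog = catalog)$mean
  }, 0)
  annual_series(mb$years, vals, name = paste0("WW ", category), unit = "g")
}
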