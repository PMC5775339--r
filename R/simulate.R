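#' Configuration for the synthetic diet-data generator
#'
#' Encodes the statistical structure the analysis pipeline assumes: a
#' two-regime occurrence process (each taxon present in a sample with a
#' regime-conditional probability, independently of other taxa),
#' right-skewed lognormal per-occurrence meal masses, and trending
#' environmental covariates. Defaults describe a Kongsfjorden-like system:
#' an Arctic-dominated regime through 2006 and a mixed regime with Atlantic
#' fishes afterwards, ~44 samples per year over 1997-2016 (~880 total),
#' Atlantic herring absent before 2013, a declining sea-ice index
#' (slope -0.5 %/yr from 19.9), warming fjord temperature (+0.1 degC/yr
#' from 0.3), and a breeding population with a within-regime decline and a
#' step in 2007.
#'
#' @param years Mass-based sampling years.
#' @param samples_per_year Samples per mass-based year (scalar or per-year
#'   vector).
#' @param regime_year Last year of the first (Arctic) regime.
#' @param binary_years Optional presence-only era years (e.g.
#'   `c(1982:1984, 1987)`); `NULL` disables the binary era.
#' @param binary_samples_per_year Samples per binary-era year.
#' @param occurrence Data frame `taxon`, `p_regime1`, `p_regime2`,
#'   `first_year` (NA = always available), `mm_g` (target mean meal mass,
#'   g) and `sdlog` (lognormal shape).
#' @param env Named list of environmental series parameters (see default).
#' @param env_years Years covered by the environmental series.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    years = 1997:2016,
    samples_per_year = 44L,
    regime_year = 2006L,
    binary_years = NULL,
    binary_samples_per_year = 25L,
    occurrence = data.frame(
      taxon = c("polar_cod", "capelin", "atlantic_herring",
                "thysanoessa_inermis", "themisto_libellula"),
      p_regime1 = c(0.80, 0.02, 0.00, 0.20, 0.15),
      p_regime2 = c(0.30, 0.35, 0.10, 0.30, 0.05),
      first_year = c(NA, NA, 2013L, NA, NA),
      mm_g = c(17.2, 15.7, 12.1, 8.0, 2.8),
      sdlog = 0.8,
      stringsAsFactors = FALSE),
    env = list(
      sea_ice_index = list(intercept = 19.9, slope = -0.5, sd = 4),
      temperature = list(intercept = 0.3, slope = 0.1, sd = 0.8),
      population_size = list(intercept1 = 167.8, slope1 = -6.9,
                             intercept2 = 80.1, slope2 = 1.4, sd = 12,
                             regime_year = 2006L),
      clutch_size = list(intercept = 1.74, slope = 0, sd = 0.08),
      breeding_success = list(intercept = 0.8, slope = 0, sd = 0.12)),
    env_years = 1997:2016) {
  stopifnot(all(occurrence$p_regime1 >= 0 & occurrence$p_regime1 <= 1),
            all(occurrence$p_regime2 >= 0 & occurrence$p_regime2 <= 1),
            all(occurrence$mm_g > 0))
  cfg <- list(years = as.integer(years),
              samples_per_year = samples_per_year,
              regime_year = as.integer(regime_year),
              binary_years = if (is.null(binary_years)) NULL else
                as.integer(binary_years),
              binary_samples_per_year = as.integer(binary_samples_per_year),
              occurrence = occurrence, env = env,
              env_years = as.integer(env_years))
  class(cfg) <- "generator_config"
  cfg
}

# lognormal meanlog giving the requested arithmetic mean
meanlog_for <- function(mean, sdlog) log(mean) - sdlog^2 / 2

#' Generate a synthetic diet sample table
#'
#' Draws, for each sample, the presence of every configured taxon as an
#' independent Bernoulli with the regime-conditional probability, then a
#' lognormal wet mass for each present taxon. Binary-era years (if
#' configured) yield presence-only samples drawn under regime-1
#' probabilities. Fixed seed gives an identical table.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @param catalog A `taxon_catalog`.
#' @return A `diet_samples` object.
#' @export
generate_samples <- function(config = generator_config(), seed = 1L,
                             catalog = default_catalog()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  occ <- config$occurrence
  colonies <- c("Krykkjefjellet", "Irgensfjellet", "unknown")
  colony_p <- c(0.45, 0.39, 0.16)
  all_years <- c(config$binary_years, config$years)
  spq <- config$samples_per_year
  meta <- list(); items <- list()
  for (yr in all_years) {
    binary <- yr %in% config$binary_years
    n_y <- if (binary) config$binary_samples_per_year
      else if (length(spq) == 1L) spq
      else spq[[as.character(yr)]]
    regime2 <- yr > config$regime_year
    p <- if (regime2) occ$p_regime2 else occ$p_regime1
    p[!is.na(occ$first_year) & yr < occ$first_year] <- 0
    ids <- sprintf("KF%d-%03d", yr, seq_len(n_y))
    stage <- sample(c("incubation", "chick_rearing"), n_y, replace = TRUE,
                    prob = c(0.16, 0.84))
    doy <- ifelse(stage == "incubation",
                  sample(166:195, n_y, replace = TRUE),
                  sample(196:235, n_y, replace = TRUE))
    meta[[length(meta) + 1L]] <- data.frame(
      sample_id = ids, year = yr,
      date = format(as.Date(doy - 1L, origin = paste0(yr, "-01-01"))),
      colony = sample(colonies, n_y, replace = TRUE, prob = colony_p),
      stage = stage,
      bird = sample(c("adult", "chick"), n_y, replace = TRUE,
                    prob = c(0.81, 0.19)),
      sex = sample(c("male", "female", "unknown"), n_y, replace = TRUE,
                   prob = c(0.32, 0.28, 0.40)),
      presence_only = binary, stringsAsFactors = FALSE)
    pres <- matrix(stats::runif(n_y * nrow(occ)) < rep(p, each = n_y),
                   nrow = n_y)
    for (j in seq_len(nrow(occ))) {
      hit <- which(pres[, j])
      if (length(hit) == 0L) next
      mass <- if (binary) NA_real_ else
        stats::rlnorm(length(hit),
                      meanlog = meanlog_for(occ$mm_g[j], occ$sdlog[j]),
                      sdlog = occ$sdlog[j])
      items[[length(items) + 1L]] <- data.frame(
        sample_id = ids[hit], taxon = occ$taxon[j],
        wet_mass_g = mass, stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, meta)
  items <- if (length(items) > 0L) do.call(rbind, items) else
    data.frame(sample_id = character(0), taxon = character(0),
               wet_mass_g = numeric(0))
  diet_samples(samples, items, catalog = catalog)
}

#' Generate synthetic environmental and demographic annual series
#'
#' Each series is a linear trend (or, for population size, a two-regime
#' line with its own intercept and slope per regime — a step plus slope
#' change) with i.i.d. Gaussian noise. Fixed seed gives identical series.
#'
#' @inheritParams generate_samples
#' @return Named list of [annual_series()]: `sea_ice_index` (%),
#'   `temperature` (degC), `population_size` (pairs), `clutch_size`
#'   (eggs/nest), `breeding_success` (chicks/nest).
#' @export
generate_env <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed + 1L)
  yrs <- config$env_years
  t0 <- yrs - min(yrs)
  out <- list()
  for (nm in names(config$env)) {
    par <- config$env[[nm]]
    mu <- if (!is.null(par$intercept1)) {
      post <- yrs > par$regime_year
      ifelse(post,
             par$intercept2 + par$slope2 * t0,
             par$intercept1 + par$slope1 * t0)
    } else {
      par$intercept + par$slope * t0
    }
    vals <- mu + stats::rnorm(length(yrs), sd = par$sd)
    unit <- switch(nm, sea_ice_index = "%", temperature = "degC", "")
    out[[nm]] <- annual_series(yrs, vals, name = nm, unit = unit)
  }
  out
}

#' Generate synthetic otolith measurements for fish in a sample table
#'
#' For each mass-based fish record of a species with a configured
#' regression, draws a per-fish otolith length within the regression's
#' valid range and emits the two otoliths of the pair with small
#' measurement jitter, so downstream pairing has realistic work to do.
#'
#' @param x A `diet_samples` object.
#' @param seed Integer seed.
#' @param regressions An `otolith_regressions` table (defines which species
#'   get otoliths and their plausible size ranges).
#' @return Data frame: `sample_id`, `species`, `otolith_mm`, `date`.
#' @export
generate_otoliths <- function(x, seed = 1L,
                              regressions = default_otolith_regressions()) {
  stopifnot(inherits(x, "diet_samples"))
  set.seed(seed + 2L)
  mb <- subset_samples(x, mass_based = TRUE)
  it <- mb$items[mb$items$taxon %in% regressions$species, , drop = FALSE]
  if (nrow(it) == 0L) {
    return(data.frame(sample_id = character(0), species = character(0),
                      otolith_mm = numeric(0), date = character(0)))
  }
  rows <- lapply(seq_len(nrow(it)), function(i) {
    reg <- regressions[regressions$species == it$taxon[i], ]
    mid <- (reg$valid_min_mm + reg$valid_max_mm) / 2
    fish_ol <- stats::rnorm(1L, mean = mid,
                            sd = (reg$valid_max_mm - reg$valid_min_mm) / 6)
    fish_ol <- min(max(fish_ol, reg$valid_min_mm), reg$valid_max_mm)
    ol <- round(fish_ol + stats::rnorm(2L, sd = 0.05), 1L)
    date <- mb$samples$date[match(it$sample_id[i], mb$samples$sample_id)]
    data.frame(sample_id = it$sample_id[i], species = it$taxon[i],
               otolith_mm = ol, date = date, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
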