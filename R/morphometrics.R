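#' Pair otolith measurements that likely came from the same fish
#'
#' Otoliths come in pairs, so within one (sample, species) the two closest
#' measurements within a tolerance are assumed to originate from the same
#' fish and are averaged; unpaired measurements pass through. Pairing is
#' greedy closest-first: the globally closest remaining pair is formed at
#' each step, which makes the result deterministic.
#'
#' @param lengths Numeric vector of otolith lengths (mm, measured to 0.1
#'   mm). Pair only within one sample and species — never across.
#' @param tolerance Maximum within-pair difference in mm (default 0.3).
#' @return Numeric vector of per-fish otolith lengths (paired values
#'   averaged), in formation order followed by unpaired values.
#' @export
pair_otoliths <- function(lengths, tolerance = 0.3) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 2L) return(lengths)
  remaining <- lengths
  paired <- numeric(0)
  repeat {
    if (length(remaining) < 2L) break
    dm <- abs(outer(remaining, remaining, "-"))
    dm[!upper.tri(dm)] <- Inf
    if (min(dm) > tolerance) break
    ij <- which(dm == min(dm), arr.ind = TRUE)[1L, ]
    paired <- c(paired, mean(remaining[ij]))
    remaining <- remaining[-ij]
  }
  c(paired, remaining)
}

#' Read an otolith-to-fish-length regression table
#'
#' @param path CSV with columns `species`, `intercept_mm`, `slope`,
#'   `valid_min_mm`, `valid_max_mm`. Slopes must be positive.
#' @return Data frame of class `otolith_regressions`.
#' @export
read_otolith_regressions <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("species", "intercept_mm", "slope", "valid_min_mm",
              "valid_max_mm")
  if (!all(needed %in% names(reg))) {
    stop("regression table needs columns: ", paste(needed, collapse = ", "))
  }
  if (any(reg$slope <= 0)) stop("otolith regression slopes must be positive")
  class(reg) <- c("otolith_regressions", "data.frame")
  reg
}

#' Built-in synthetic placeholder otolith regressions
#'
#' Plausibility-shaped stand-in coefficients shipped with the package (see
#' the file header of `otolith_regressions_synthetic.csv`); substitute
#' published species-specific regressions for real analyses.
#' @return An `otolith_regressions` data frame.
#' @export
default_otolith_regressions <- function() {
  read_otolith_regressions(system.file(
    "extdata", "otolith_regressions_synthetic.csv",
    package = "dietshift", mustWork = TRUE))
}

#' Estimate fish length from otolith length
#'
#' Applies the species' linear regression, flags estimates from otoliths
#' outside the regression's valid range as extrapolated, and optionally
#' applies a shrinkage correction factor (frozen reference material can
#' shrink otoliths, biasing lengths low by a few percent).
#'
#' @param otolith_mm Numeric vector of (per-fish) otolith lengths, mm > 0.
#' @param species Single species key present in `regressions`.
#' @param regressions An `otolith_regressions` table.
#' @param shrinkage_factor Multiplier on the estimated length, typically in
#'   \[1.00, 1.04\] (default 1 = no correction).
#' @return Data frame: `otolith_mm`, `fish_length_mm`, `extrapolated`.
#' @export
estimate_length <- function(otolith_mm, species,
                            regressions = default_otolith_regressions(),
                            shrinkage_factor = 1) {
  otolith_mm <- as.numeric(otolith_mm)
  if (any(otolith_mm <= 0)) stop("otolith lengths must be positive")
  if (shrinkage_factor < 1 || shrinkage_factor > 1.1) {
    stop("shrinkage_factor should be a modest upward correction (1 to 1.1)")
  }
  row <- regressions[regressions$species == species, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop("no otolith regression for species '", species, "'")
  }
  len <- (row$intercept_mm + row$slope * otolith_mm) * shrinkage_factor
  data.frame(
    otolith_mm = otolith_mm,
    fish_length_mm = len,
    extrapolated = otolith_mm < row$valid_min_mm |
      otolith_mm > row$valid_max_mm)
}

#' Read a length-at-age key
#'
#' @param path CSV with columns `species` and strictly increasing
#'   `cutoff_1` .. `cutoff_5` (mm).
#' @return Data frame of class `age_key`.
#' @export
read_age_key <- function(path) {
  key <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  cuts <- paste0("cutoff_", 1:5)
  if (!all(c("species", cuts) %in% names(key))) {
    stop("age key needs columns species, ", paste(cuts, collapse = ", "))
  }
  for (i in seq_len(nrow(key))) {
    v <- as.numeric(key[i, cuts])
    if (any(diff(v) <= 0)) {
      stop("age cutoffs must be strictly increasing for ", key$species[i])
    }
  }
  class(key) <- c("age_key", "data.frame")
  key
}

#' Built-in synthetic placeholder age key
#' @return An `age_key` data frame (see [default_otolith_regressions()] for
#'   the stand-in caveat).
#' @export
default_age_key <- function() {
  read_age_key(system.file("extdata", "age_key_synthetic.csv",
                           package = "dietshift", mustWork = TRUE))
}

age_class_labels <- function() c("0+", "1", "2", "3", "4", ">4")

#' Assign age classes from estimated fish lengths
#'
#' Age is a step function of length: below the first cutoff is 0+ (by
#' convention, any length below the smallest cutoff), beyond the last is
#' ">4". For 0+ fish with a capture date, the elapsed days since a
#' configurable spawning window are reported (min counted from the window
#' end, max from the window start) — useful for checking whether
#' young-of-the-year could have drifted in from distant spawning grounds.
#'
#' @param length_mm Numeric vector of fish lengths (mm).
#' @param species Single species key present in `key`.
#' @param key An `age_key`.
#' @param capture_date Optional capture `Date` (scalar or vector) for the
#'   0+ day counts.
#' @param spawning_window Month-day start/end of the spawning period,
#'   `c("02-15", "04-01")` by default (late-winter coastal spawning).
#' @return Data frame: `length_mm`, `age_class`, and when `capture_date` is
#'   given, `days_since_spawning_min`/`_max` (NA for classes other than 0+).
#' @export
assign_age <- function(length_mm, species, key = default_age_key(),
                       capture_date = NULL,
                       spawning_window = c("02-15", "04-01")) {
  row <- key[key$species == species, , drop = FALSE]
  if (nrow(row) == 0L) stop("no age key for species '", species, "'")
  cuts <- as.numeric(row[paste0("cutoff_", 1:5)])
  cls <- age_class_labels()[findInterval(length_mm, cuts) + 1L]
  out <- data.frame(length_mm = as.numeric(length_mm), age_class = cls,
                    stringsAsFactors = FALSE)
  if (!is.null(capture_date)) {
    capture_date <- as.Date(capture_date)
    yr <- format(capture_date, "%Y")
    win_start <- as.Date(paste0(yr, "-", spawning_window[1]))
    win_end <- as.Date(paste0(yr, "-", spawning_window[2]))
    is0 <- cls == "0+"
    out$days_since_spawning_min <-
      ifelse(is0, as.numeric(capture_date - win_end), NA_real_)
    out$days_since_spawning_max <-
      ifelse(is0, as.numeric(capture_date - win_start), NA_real_)
  }
  out
}

#' Batch fish-length and age reconstruction for a morphometrics table
#'
#' Runs otolith pairing, length regression and age assignment per
#' (sample, species) group of a long measurement table.
#'
#' @param measurements Data frame with columns `sample_id`, `species`,
#'   `otolith_mm`, optionally `date`.
#' @param regressions An `otolith_regressions` table.
#' @param key An `age_key`.
#' @param tolerance Otolith pairing tolerance (mm).
#' @param shrinkage_factor Passed to [estimate_length()].
#' @return Data frame: `sample_id`, `species`, `otolith_mm` (per fish,
#'   after pairing), `fish_length_mm`, `extrapolated`, `age_class`. Species
#'   lacking a regression are dropped with a warning.
#' @export
morphometrics_table <- function(measurements,
                                regressions = default_otolith_regressions(),
                                key = default_age_key(), tolerance = 0.3,
                                shrinkage_factor = 1) {
  stopifnot(all(c("sample_id", "species", "otolith_mm") %in%
                  names(measurements)))
  known <- measurements$species %in% regressions$species
  if (any(!known)) {
    warning("no regression for species: ",
            paste(unique(measurements$species[!known]), collapse = ", "))
    measurements <- measurements[known, , drop = FALSE]
  }
  groups <- split(measurements,
                  list(measurements$sample_id, measurements$species),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    fish <- pair_otoliths(g$otolith_mm, tolerance = tolerance)
    est <- estimate_length(fish, g$species[1L], regressions,
                           shrinkage_factor = shrinkage_factor)
    date <- if ("date" %in% names(g)) g$date[1L] else NULL
    age <- if (g$species[1L] %in% key$species) {
      assign_age(est$fish_length_mm, g$species[1L], key,
                 capture_date = if (!is.null(date) && !is.na(date)) date)
    } else {
      data.frame(age_class = NA_character_)
    }
    data.frame(sample_id = g$sample_id[1L], species = g$species[1L],
               otolith_mm = est$otolith_mm,
               fish_length_mm = est$fish_length_mm,
               extrapolated = est$extrapolated,
               age_class = age$age_class, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
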