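#' Construct a diet sample table
#'
#' The central container for regurgitate data: one row per sample in
#' `samples` (metadata) and one row per (sample, prey taxon) in `items`.
#' Samples flagged `presence_only` carry no mass information (binary-era
#' records) and are usable only for occurrence-based metrics; an empty item
#' list is a valid, retained sample (an empty regurgitate still counts in
#' frequency-of-occurrence denominators).
#'
#' @param samples Data frame with columns `sample_id` (unique), `year`
#'   (integer), and optionally `date`, `colony`, `stage`, `bird`, `sex`,
#'   `presence_only` (logical/0-1). Missing categorical fields are filled
#'   with `"unknown"`.
#' @param items Data frame with columns `sample_id`, `taxon`, and optionally
#'   `wet_mass_g`, `count`, `otolith_lengths_mm` (semicolon-separated mm
#'   values as a character string).
#' @param catalog A `taxon_catalog`, used to flag taxa absent from the
#'   catalog in the load report.
#' @return An object of class `diet_samples`: a list with elements
#'   `samples`, `items`, `n_samples` and `years`, carrying a `load_report`
#'   attribute.
#' @export
diet_samples <- function(samples, items, catalog = default_catalog()) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "year") %in% names(samples))) {
    stop("`samples` needs columns sample_id and year")
  }
  if (nrow(items) > 0L && !all(c("sample_id", "taxon") %in% names(items))) {
    stop("`items` needs columns sample_id and taxon")
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id in sample table: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  samples$year <- as.integer(samples$year)
  if (anyNA(samples$year)) stop("every sample needs a parseable year")
  for (col in c("colony", "stage", "bird", "sex")) {
    if (is.null(samples[[col]])) samples[[col]] <- "unknown"
    samples[[col]][is.na(samples[[col]]) | samples[[col]] == ""] <- "unknown"
  }
  if (is.null(samples$date)) samples$date <- NA_character_
  if (is.null(samples$presence_only)) samples$presence_only <- FALSE
  samples$presence_only <- as.logical(samples$presence_only) %in% TRUE

  if (nrow(items) > 0L) {
    items$sample_id <- as.character(items$sample_id)
    orphan <- setdiff(items$sample_id, samples$sample_id)
    if (length(orphan) > 0L) {
      stop("items refer to unknown sample_id(s): ",
           paste(utils::head(orphan, 5L), collapse = ", "))
    }
    if (is.null(items$wet_mass_g)) items$wet_mass_g <- NA_real_
    items$wet_mass_g <- as.numeric(items$wet_mass_g)
    if (any(items$wet_mass_g < 0, na.rm = TRUE)) {
      bad <- items$sample_id[which(items$wet_mass_g < 0)][1L]
      stop("negative wet mass in sample ", bad)
    }
    if (is.null(items$count)) items$count <- NA_integer_
    if (is.null(items$otolith_lengths_mm)) items$otolith_lengths_mm <- ""
    items$otolith_lengths_mm[is.na(items$otolith_lengths_mm)] <- ""
    key <- paste(items$sample_id, items$taxon, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)]
      for (k in unique(dup)) {
        m <- items$wet_mass_g[key == k]
        if (length(unique(stats::na.omit(m))) > 1L) {
          stop("conflicting wet masses for sample ",
               sub("\r.*", "", k), ", taxon ", sub(".*\r", "", k))
        }
      }
      warning("collapsing duplicated (sample_id, taxon) rows with identical mass")
      items <- items[!duplicated(key), , drop = FALSE]
    }
    # presence-only samples must not carry masses
    po <- samples$sample_id[samples$presence_only]
    items$wet_mass_g[items$sample_id %in% po] <- NA_real_
  }

  flagged <- character(0)
  if (nrow(items) > 0L) {
    flagged <- unique(items$taxon[!(items$taxon %in% catalog$taxon)])
  }
  out <- list(
    samples = samples,
    items = items,
    n_samples = nrow(samples),
    years = sort(unique(samples$year))
  )
  class(out) <- "diet_samples"
  attr(out, "load_report") <- list(
    n_samples = nrow(samples),
    n_item_rows = nrow(items),
    unknown_taxa = flagged
  )
  out
}

#' @export
print.diet_samples <- function(x, ...) {
  cat("Diet sample table: ", x$n_samples, " samples, ",
      nrow(x$items), " prey records, years ",
      min(x$years), "-", max(x$years), "\n", sep = "")
  n_po <- sum(x$samples$presence_only)
  if (n_po > 0L) cat("  presence-only (binary-era) samples: ", n_po, "\n", sep = "")
  rep <- attr(x, "load_report")
  if (length(rep$unknown_taxa) > 0L) {
    cat("  taxa not in catalog: ", paste(rep$unknown_taxa, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Read a long-format diet sample CSV
#'
#' Expects the long schema: one row per (sample, taxon) with columns
#' `sample_id`, `date`, `year`, `colony`, `stage`, `bird`, `sex`, `taxon`,
#' `wet_mass_g`, `count`, `otolith_lengths_mm`, `presence_only`. Rows with
#' an empty `taxon` declare an empty sample. Samples lacking a date must
#' provide `year` directly.
#'
#' @param path CSV path. Lines starting with `#` are skipped.
#' @param catalog A `taxon_catalog`.
#' @return A `diet_samples` object; `attr(, "load_report")` records parsed
#'   and flagged row counts.
#' @export
read_samples <- function(path, catalog = default_catalog()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                         colClasses = "character")
  if (!"sample_id" %in% names(raw)) stop("samples CSV needs a sample_id column")
  if (is.null(raw$year) || any(raw$year == "" | is.na(raw$year))) {
    if (is.null(raw$date)) stop("need a year or date column for every row")
    yr_from_date <- substr(raw$date, 1L, 4L)
    if (is.null(raw$year)) raw$year <- yr_from_date
    miss <- raw$year == "" | is.na(raw$year)
    raw$year[miss] <- yr_from_date[miss]
  }
  meta_cols <- intersect(
    c("sample_id", "date", "year", "colony", "stage", "bird", "sex",
      "presence_only"), names(raw))
  samples <- unique(raw[meta_cols])
  if (anyDuplicated(samples$sample_id)) {
    stop("inconsistent metadata across rows of sample(s): ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  has_item <- !is.null(raw$taxon) & !(raw$taxon %in% c("", NA))
  item_cols <- intersect(
    c("sample_id", "taxon", "wet_mass_g", "count", "otolith_lengths_mm"),
    names(raw))
  items <- raw[has_item, item_cols, drop = FALSE]
  diet_samples(samples, items, catalog = catalog)
}

#' Write a diet sample table to CSV (long format)
#'
#' Inverse of [read_samples()]: the written file reads back to the same
#' table up to row order.
#'
#' @param x A `diet_samples` object.
#' @param path Output CSV path.
#' @param header Optional character vector of `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_samples <- function(x, path, header = NULL) {
  stopifnot(inherits(x, "diet_samples"))
  long <- merge(x$samples, x$items, by = "sample_id", all.x = TRUE, sort = FALSE)
  ord <- c("sample_id", "date", "year", "colony", "stage", "bird", "sex",
           "taxon", "wet_mass_g", "count", "otolith_lengths_mm",
           "presence_only")
  long <- long[order(long$sample_id), intersect(ord, names(long)), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(long, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Subset a diet sample table
#'
#' @param x A `diet_samples` object.
#' @param years Optional vector of years to keep.
#' @param mass_based If `TRUE`, drop presence-only samples.
#' @param sample_ids Optional explicit sample ids.
#' @return A `diet_samples` object.
#' @export
subset_samples <- function(x, years = NULL, mass_based = FALSE,
                           sample_ids = NULL) {
  stopifnot(inherits(x, "diet_samples"))
  keep <- rep(TRUE, nrow(x$samples))
  if (!is.null(years)) keep <- keep & x$samples$year %in% years
  if (mass_based) keep <- keep & !x$samples$presence_only
  if (!is.null(sample_ids)) keep <- keep & x$samples$sample_id %in% sample_ids
  samples <- x$samples[keep, , drop = FALSE]
  items <- x$items[x$items$sample_id %in% samples$sample_id, , drop = FALSE]
  out <- list(samples = samples, items = items,
              n_samples = nrow(samples), years = sort(unique(samples$year)))
  class(out) <- "diet_samples"
  attr(out, "load_report") <- attr(x, "load_report")
  out
}

#' Per-sample wet mass of an origin class
#'
#' Sums the wet mass of all prey items whose catalog origin matches, per
#' sample; a sample containing no matching prey scores 0 g. Taxa with origin
#' `unidentified` never contribute to any named origin class.
#'
#' @param x A `diet_samples` object containing only mass-based samples
#'   (see [subset_samples()]); presence-only samples have no masses and are
#'   refused.
#' @param origin One of [origin_classes()].
#' @param catalog A `taxon_catalog`.
#' @return Named numeric vector (grams), one entry per sample.
#' @export
origin_mass <- function(x, origin, catalog = default_catalog()) {
  stopifnot(inherits(x, "diet_samples"))
  origin <- match.arg(origin, origin_classes())
  if (any(x$samples$presence_only)) {
    stop("origin_mass needs mass-based samples; ",
         "presence-only samples carry no wet mass (subset first)")
  }
  out <- stats::setNames(numeric(x$n_samples), x$samples$sample_id)
  if (nrow(x$items) > 0L) {
    it <- x$items[origin_of(x$items$taxon, catalog) == origin, , drop = FALSE]
    if (nrow(it) > 0L) {
      s <- tapply(it$wet_mass_g, it$sample_id, sum, na.rm = TRUE)
      out[names(s)] <- as.numeric(s)
    }
  }
  out
}

#' Per-sample total wet mass
#'
#' Total measured wet mass per sample, across all items including
#' unidentified material.
#'
#' @inheritParams origin_mass
#' @return Named numeric vector (grams).
#' @export
total_mass <- function(x) {
  stopifnot(inherits(x, "diet_samples"))
  if (any(x$samples$presence_only)) {
    stop("total_mass needs mass-based samples (subset first)")
  }
  out <- stats::setNames(numeric(x$n_samples), x$samples$sample_id)
  if (nrow(x$items) > 0L) {
    s <- tapply(x$items$wet_mass_g, x$items$sample_id, sum, na.rm = TRUE)
    out[names(s)] <- as.numeric(s)
  }
  out
}

#' Year-by-category presence count matrix
#'
#' Counts, per year and category, the number of samples containing the
#' category. Presence-only (binary-era) samples enter identically to
#' mass-based ones, which is what lets occurrence metrics span both eras.
#' Years with no samples are absent from the result rather than zero-filled.
#'
#' @param x A `diet_samples` object.
#' @param level `"taxon"` for raw taxa (unidentified taxa included) or
#'   `"origin"` for origin classes (the `unidentified` class excluded).
#' @param catalog A `taxon_catalog`.
#' @return Integer matrix, years in rows; attribute `n_samples` holds the
#'   per-year sample counts (the row margins' denominators).
#' @export
presence_matrix <- function(x, level = c("taxon", "origin"),
                            catalog = default_catalog()) {
  stopifnot(inherits(x, "diet_samples"))
  level <- match.arg(level)
  if (x$n_samples == 0L) stop("empty sample table")
  years <- x$years
  n_by_year <- table(factor(x$samples$year, levels = years))
  it <- x$items
  if (level == "origin") {
    it$category <- origin_of(it$taxon, catalog)
    it <- it[it$category != "unidentified", , drop = FALSE]
    cats <- intersect(setdiff(origin_classes(), "unidentified"),
                      unique(it$category))
  } else {
    it$category <- it$taxon
    cats <- sort(unique(it$category))
  }
  m <- matrix(0L, nrow = length(years), ncol = length(cats),
              dimnames = list(as.character(years), cats))
  if (nrow(it) > 0L) {
    yr <- x$samples$year[match(it$sample_id, x$samples$sample_id)]
    pres <- unique(data.frame(year = yr, sample_id = it$sample_id,
                              category = it$category))
    tab <- table(factor(pres$year, levels = years),
                 factor(pres$category, levels = cats))
    m[] <- as.integer(tab)
  }
  attr(m, "n_samples") <- stats::setNames(as.integer(n_by_year),
                                          as.character(years))
  m
}
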