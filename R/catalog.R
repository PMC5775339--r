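#' Read a taxon catalog
#'
#' A taxon catalog maps taxon keys to a common name, a coarse group
#' (fish / crustacea / other), a subgroup label and a biogeographic origin
#' class. Origin classes drive all Arctic-vs-Atlantic aggregation:
#' `arctic`, `atlantic`, `mesopelagic`, `intermediate` and `unidentified`.
#' Taxa with origin `unidentified` are retained in taxon-level summaries but
#' always excluded from origin-level aggregates, because unidentifiable
#' material cannot be attributed to a water mass.
#'
#' @param path Path to a CSV file with columns `taxon`, `common_name`,
#'   `group`, `subgroup`, `origin`.
#' @return A data frame of class `taxon_catalog`.
#' @seealso [default_catalog()] for the built-in Kongsfjorden catalog.
#' @export
read_catalog <- function(path) {
  cat <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("taxon", "common_name", "group", "subgroup", "origin")
  missing <- setdiff(required, names(cat))
  if (length(missing) > 0L) {
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(cat$taxon)) {
    stop("catalog contains duplicated taxon keys: ",
         paste(unique(cat$taxon[duplicated(cat$taxon)]), collapse = ", "))
  }
  bad_group <- setdiff(cat$group, c("fish", "crustacea", "other"))
  if (length(bad_group) > 0L) {
    stop("unknown group value(s): ", paste(bad_group, collapse = ", "))
  }
  bad_origin <- setdiff(cat$origin, origin_classes())
  if (length(bad_origin) > 0L) {
    stop("unknown origin value(s): ", paste(bad_origin, collapse = ", "))
  }
  class(cat) <- c("taxon_catalog", "data.frame")
  cat
}

#' Built-in taxon catalog for Kongsfjorden kittiwake diet items
#'
#' Covers every prey taxon recorded in the long-term Kongsfjorden regurgitate
#' series. Origin membership follows the standard division for this system:
#' polar cod and *Themisto libellula* are Arctic; capelin, Atlantic herring,
#' Atlantic cod and haddock are Atlantic; glacier lanternfish, white
#' barracudina and *Pasiphaea tarda* are mesopelagic; the remaining
#' identified taxa are intermediate. Unidentified fish and crustaceans carry
#' origin `unidentified`. The catalog is a plain CSV under
#' `inst/extdata`, so users can copy and edit it to override memberships.
#'
#' @return A `taxon_catalog` data frame.
#' @export
default_catalog <- function() {
  read_catalog(system.file("extdata", "taxon_catalog.csv",
                           package = "dietshift", mustWork = TRUE))
}

#' Origin classes recognised by the package
#' @return Character vector of valid origin labels.
#' @export
origin_classes <- function() {
  c("arctic", "atlantic", "mesopelagic", "intermediate", "unidentified")
}

#' Look up the origin class of taxa
#'
#' @param taxa Character vector of taxon keys.
#' @param catalog A `taxon_catalog`.
#' @return Character vector of origin classes; taxa absent from the catalog
#'   map to `"unidentified"`.
#' @export
origin_of <- function(taxa, catalog = default_catalog()) {
  idx <- match(taxa, catalog$taxon)
  out <- catalog$origin[idx]
  out[is.na(idx)] <- "unidentified"
  out
}
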