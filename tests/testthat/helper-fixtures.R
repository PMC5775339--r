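# Shared fixtures and independent oracles, built in code.

# A 3-sample mass-based toy table: hand-checkable in every metric.
#   S1: polar cod 10 g, krill 2 g       (total 12)
#   S2: capelin 5 g, herring 3 g        (total 8)
#   S3: unidentified fish 7 g           (total 7)
toy_table <- function() {
  diet_samples(
    samples = data.frame(
      sample_id = c("S1", "S2", "S3"), year = 2005L,
      colony = "Krykkjefjellet", stage = "chick_rearing",
      bird = "adult", sex = "unknown", presence_only = FALSE),
    items = data.frame(
      sample_id = c("S1", "S1", "S2", "S2", "S3"),
      taxon = c("polar_cod", "thysanoessa_inermis", "capelin",
                "atlantic_herring", "unidentified_fish"),
      wet_mass_g = c(10, 2, 5, 3, 7)))
}

# Table builder: n samples in one year, the first n_occ containing `taxon`
# at a fixed mass each. Extra list(taxon=, n_occ=, mass=) groups stack.
occurrence_table <- function(n, groups, year = 2000L, stage = NULL) {
  ids <- sprintf("S%04d", seq_len(n))
  items <- do.call(rbind, lapply(groups, function(g) {
    data.frame(sample_id = ids[seq_len(g$n_occ)], taxon = g$taxon,
               wet_mass_g = g$mass, stringsAsFactors = FALSE)
  }))
  samples <- data.frame(sample_id = ids, year = year,
                        presence_only = FALSE, stringsAsFactors = FALSE)
  if (!is.null(stage)) samples$stage <- stage
  diet_samples(samples, items)
}

# Independent Ward oracle: greedy minimum increase in within-cluster error
# sum of squares, computed from explicit 1-D coordinates (closed form:
# merge cost |A||B|/(|A|+|B|) * (mean_A - mean_B)^2). Returns the merge
# sequence as sets of original point indices.
ward_ess_oracle <- function(coords) {
  clusters <- lapply(seq_along(coords), identity)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL; best_cost <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        a <- coords[clusters[[i]]]; b <- coords[clusters[[j]]]
        cost <- length(a) * length(b) / (length(a) + length(b)) *
          (mean(a) - mean(b))^2
        if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# Leaf sets produced by each hclust merge, for comparison with the oracle.
hclust_merge_sets <- function(h) {
  sets <- vector("list", nrow(h$merge))
  for (k in seq_len(nrow(h$merge))) {
    row <- h$merge[k, ]
    members <- unlist(lapply(row, function(m) {
      if (m < 0) -m else sets[[m]]
    }))
    sets[[k]] <- sort(members)
  }
  sets
}
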