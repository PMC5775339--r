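#' Bray-Curtis dissimilarity among years
#'
#' Computes the Bray-Curtis dissimilarity
#' d(i,j) = sum|x_ik - x_jk| / sum(x_ik + x_jk) between the rows of a
#' year-by-taxon composition matrix (typically annual frequency-of-occurrence
#' values). Bray-Curtis is bounded in \[0, 1\], symmetric and zero on the
#' diagonal, but is only a semimetric: the triangle inequality can fail.
#'
#' @param m Non-negative numeric matrix, years in rows (rownames = years).
#' @return A `dist` object with year labels.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("composition matrix must be non-negative")
  zero_rows <- rownames(m)[rowSums(m) == 0]
  if (length(zero_rows) > 0L) {
    stop("all-zero composition row(s): ", paste(zero_rows, collapse = ", "))
  }
  vegan::vegdist(m, method = "bray")
}

#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with Ward's criterion in its `ward.D2` variant,
#' which squares the supplied dissimilarities internally — the correct form
#' when the input is a plain (unsquared) dissimilarity matrix such as
#' Bray-Curtis. Merge heights are non-decreasing.
#'
#' @param d A `dist` object (see [bray_curtis()]).
#' @return An `hclust` tree with year leaf labels.
#' @export
ward_cluster <- function(d) {
  d <- stats::as.dist(d)
  if (attr(d, "Size") < 2L) stop("clustering needs at least 2 observations")
  stats::hclust(d, method = "ward.D2")
}

#' Export a dendrogram to Newick
#'
#' Branch lengths are differences of merge heights, so root-to-leaf path
#' lengths reproduce the dendrogram geometry.
#'
#' @param h An `hclust` tree.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(h, path) {
  stopifnot(inherits(h, "hclust"))
  phy <- ape::as.phylo(h)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal-style nMDS: iterative stress minimisation over monotone-regressed
#' dissimilarities, restarted from random configurations and keeping the
#' best solution. Stress is reported on the 0-1 scale; values near zero mean
#' the rank order of input dissimilarities is reproduced almost exactly.
#' Orientation is arbitrary (any rotation/reflection of the coordinates has
#' identical stress), so downstream comparisons should use stress or
#' inter-point distances, never raw coordinates.
#'
#' @param d A `dist` object.
#' @param k Number of ordination dimensions (default 2).
#' @param seed Integer seed; fixed seed gives a reproducible configuration.
#' @param n_restarts Number of random starts (default 20).
#' @param max_iter Maximum iterations per start.
#' @return A list of class `ordination_result`: `points` (n x k, centred),
#'   `stress`, `converged`, `k`, `seed`.
#' @export
nmds <- function(d, k = 2L, seed = 1L, n_restarts = 20L, max_iter = 200L) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k < 1L || k >= n) stop("need 1 <= k < number of observations")
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, try = n_restarts, trymax = n_restarts,
                        maxit = max_iter, trace = 0, autotransform = FALSE,
                        wascores = FALSE)
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  colnames(pts) <- paste0("dim", seq_len(k))
  out <- list(points = pts, stress = fit$stress,
              converged = isTRUE(fit$converged) || fit$converged > 0,
              k = k, seed = seed)
  class(out) <- "ordination_result"
  out
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("nMDS ordination: %d points in %d dimensions, stress = %.4f%s\n",
              nrow(x$points), x$k, x$stress,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Species scores for an ordination
#'
#' Places each taxon at the weighted average of the year coordinates, with
#' that taxon's composition values (e.g. annual FO) as weights — taxa plot
#' near the years in which they occur most. Taxa with zero total weight have
#' no defined position and are dropped with a warning.
#'
#' @param ord An `ordination_result` (or a plain coordinate matrix with year
#'   rownames).
#' @param m The year-by-taxon composition matrix used for the ordination.
#' @return Matrix of taxon scores (taxa x k).
#' @export
species_scores <- function(ord, m) {
  pts <- if (inherits(ord, "ordination_result")) ord$points else as.matrix(ord)
  m <- as.matrix(m)
  if (!setequal(rownames(pts), rownames(m))) {
    stop("ordination and composition matrix must cover the same years")
  }
  m <- m[rownames(pts), , drop = FALSE]
  tot <- colSums(m)
  drop <- colnames(m)[tot == 0]
  if (length(drop) > 0L) {
    warning("dropping taxa never present: ", paste(drop, collapse = ", "))
    m <- m[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  sc <- t(m) %*% pts / tot
  colnames(sc) <- colnames(pts)
  sc
}
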