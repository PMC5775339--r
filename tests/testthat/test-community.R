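test_that("Bray-Curtis matches the hand formula and its bounds", {
  m <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(as.numeric(bray_curtis(m)), 1)
  m2 <- rbind(a = c(3, 2, 5), b = c(3, 2, 5))
  expect_equal(as.numeric(bray_curtis(m2)), 0)
  m3 <- rbind(a = c(2, 1), b = c(1, 1))
  expect_equal(as.numeric(bray_curtis(m3)), 0.2)
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))),
               "all-zero.*a")
  expect_error(bray_curtis(rbind(a = c(-1, 2), b = c(1, 1))),
               "non-negative")
})

test_that("Bray-Curtis is a bounded semimetric on random FO matrices", {
  set.seed(31)
  for (i in 1:5) {
    m <- matrix(runif(60, 0.01, 100), nrow = 6)
    rownames(m) <- paste0("y", 1:6)
    d <- as.matrix(bray_curtis(m))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 6))
  }
})

test_that("identical rows merge first, at height zero", {
  m <- rbind(a = c(5, 1), b = c(5, 1), c = c(1, 9))
  h <- ward_cluster(bray_curtis(m))
  expect_equal(sort(h$merge[1, ]), c(-2, -1))
  expect_equal(h$height[1], 0)
})

test_that("Ward merge order matches the greedy minimum-ESS oracle", {
  coords <- c(0, 1, 10, 12)
  h <- ward_cluster(dist(coords))
  expect_equal(hclust_merge_sets(h), ward_ess_oracle(coords))
  # and on a second, less regular instance
  coords2 <- c(0, 3, 4, 20, 21, 35)
  h2 <- ward_cluster(dist(coords2))
  expect_equal(hclust_merge_sets(h2), ward_ess_oracle(coords2))
  expect_true(all(diff(h2$height) >= -1e-12))
  expect_error(ward_cluster(dist(1)), "at least 2")
})

test_that("a cut at k = 2 separates the two regimes of generated data", {
  ok <- 0L
  for (seed in 1:10) {
    x <- generate_samples(seed = seed)
    pm <- presence_matrix(x, level = "taxon")
    fo <- 100 * sweep(pm, 1, attr(pm, "n_samples"), "/")
    h <- ward_cluster(bray_curtis(fo))
    grp <- stats::cutree(h, k = 2)
    truth <- as.integer(as.integer(rownames(fo)) > 2006) + 1L
    if (length(unique(tapply(truth, grp, mean))) == 2 &&
        all(tapply(truth, grp, function(v) length(unique(v))) == 1)) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok, 9L)
})

test_that("nMDS embeds Euclidean configurations with near-zero stress", {
  set.seed(7)
  pts <- matrix(rnorm(16), 8, 2)
  rownames(pts) <- paste0("y", 1:8)
  ord <- suppressWarnings(nmds(dist(pts), k = 2, seed = 3))
  expect_lt(ord$stress, 0.01)
  expect_equal(dim(ord$points), c(8L, 2L))
  expect_equal(unname(colMeans(ord$points)), c(0, 0))
  # same seed, same result
  ord2 <- suppressWarnings(nmds(dist(pts), k = 2, seed = 3))
  expect_equal(ord$points, ord2$points)
  expect_error(nmds(dist(pts), k = 9), "k < number")
})

test_that("stress does not increase with added dimensions", {
  set.seed(12)
  m <- matrix(runif(50, 1, 100), nrow = 10)
  rownames(m) <- paste0("y", 1:10)
  d <- bray_curtis(m)
  s1 <- suppressWarnings(nmds(d, k = 1, seed = 2)$stress)
  s2 <- suppressWarnings(nmds(d, k = 2, seed = 2)$stress)
  s3 <- suppressWarnings(nmds(d, k = 3, seed = 2)$stress)
  expect_lte(s2, s1 + 1e-6)
  expect_lte(s3, s2 + 1e-6)
})

test_that("species scores are FO-weighted year averages", {
  pts <- rbind(y1 = c(1, 0), y2 = c(-1, 0), y3 = c(0, 2))
  pts <- scale(pts, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  m <- cbind(only_y1 = c(10, 0, 0), everywhere = c(5, 5, 5),
             split31 = c(3, 1, 0), never = c(0, 0, 0))
  rownames(m) <- rownames(pts)
  expect_warning(sc <- species_scores(pts, m), "never present")
  expect_equal(unname(sc["only_y1", ]), unname(pts["y1", ]))
  expect_equal(unname(sc["everywhere", ]), unname(colMeans(pts)))
  expect_equal(unname(sc["split31", ]),
               unname((3 * pts["y1", ] + 1 * pts["y2", ]) / 4))
  expect_false("never" %in% rownames(sc))
})
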