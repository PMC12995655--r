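test_that("standardization gives unit-scale columns and a reusable scaler", {
  withr::with_seed(3, delta <- hand_delta(rnorm(10, 5, 2), rnorm(10, -1, 0.5)))
  std <- standardize_deltas(delta)
  expect_equal(colMeans(std$points), c(delta_upper = 0, delta_lower = 0),
               tolerance = 1e-12)
  expect_equal(apply(std$points, 2, sd), c(delta_upper = 1, delta_lower = 1),
               tolerance = 1e-12)
  back <- respsig:::apply_scaler(std$scaler,
                                 delta[, c("delta_upper", "delta_lower")])
  expect_equal(unname(back), unname(std$points), tolerance = 1e-12)
  const <- hand_delta(rep(1, 5), rnorm(5))
  expect_error(standardize_deltas(const), "delta_upper")
})

test_that("Ward clustering splits collinear points at the large gap", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(ward_cluster(pts, 2), c(1L, 1L, 2L, 2L))
  expect_equal(ward_cluster(pts, 4), 1:4)
  expect_error(ward_cluster(pts, 1), "k")
  expect_error(ward_cluster(pts, 5), "k")
})

test_that("Ward k = 2 attains the exhaustive minimum within-cluster sum of squares", {
  wss_of <- function(points, labels) {
    sum(vapply(unique(labels), function(cl) {
      X <- points[labels == cl, , drop = FALSE]
      sum(sweep(X, 2, colMeans(X))^2)
    }, numeric(1)))
  }
  # agglomerative Ward is greedy, so global-optimum agreement is a property
  # of the separated regime (the regime the responder data occupy), not of
  # arbitrary point sets; checked across seeds at clear blob separation
  for (s in 1:6) {
    blobs <- make_blobs(c(4, 4), list(c(0, 0), c(3, 3)), spread = 0.6,
                        seed = 200 + s)
    oracle <- brute_min_wss_k2(blobs$points)
    labels <- ward_cluster(blobs$points, 2)
    expect_equal(wss_of(blobs$points, labels), oracle$wss, tolerance = 1e-9)
  }
  # the collinear hand case, against the same oracle
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(brute_min_wss_k2(pts)$labels, c(1, 1, 2, 2))
})

test_that("silhouette matches the direct a/b computation and flags misassignment", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
  s <- silhouette_score(pts, c(1, 1, 2, 2))
  # per-point widths computed by hand from pairwise distances
  b1 <- mean(c(sqrt(200), sqrt(221))); b2 <- mean(c(sqrt(181), sqrt(200)))
  expect_equal(s, mean(c((b1 - 1) / b1, (b2 - 1) / b2,
                         (b2 - 1) / b2, (b1 - 1) / b1)), tolerance = 1e-12)
  expect_equal(round(s, 3), 0.929)
  # splitting two coincident groups across labels is penalized
  coincident <- rbind(c(0, 0), c(0, 1), c(0, 0), c(0, 1))
  expect_lte(silhouette_score(coincident, c(1, 2, 2, 1)), 0)
  expect_error(silhouette_score(pts, rep(1, 4)), "clusters")
})

test_that("silhouette agrees with the cluster package on random data", {
  skip_if_not_installed("cluster")
  withr::with_seed(50, pts <- matrix(rnorm(40), ncol = 2))
  for (k in 2:4) {
    labels <- ward_cluster(pts, k)
    ref <- mean(cluster::silhouette(labels, dist(pts))[, "sil_width"])
    expect_equal(silhouette_score(pts, labels), ref, tolerance = 1e-9)
  }
})

test_that("k selection prefers the silhouette maximum among guarded candidates", {
  blobs <- make_blobs(c(12, 15), list(c(0, 0), c(4, 4)), seed = 61)
  sol <- select_k(blobs$points, 2:4, min_cluster_size = 5)
  expect_equal(sol$k, 2)
  expect_equal(sort(sol$sizes), c(12, 15))
  expect_equal(sol$candidates$k, 2:4)
  three <- make_blobs(c(8, 8, 8), list(c(0, 0), c(6, 0), c(3, 6)), seed = 62)
  expect_equal(select_k(three$points, 2:4, min_cluster_size = 5)$k, 3)
})

test_that("the small-cluster guard applies the documented selection rule", {
  candidates <- data.frame(k = 2:4, silhouette = c(0.6, 0.7, 0.8),
                           min_size = c(12, 3, 3))
  expect_equal(respsig:::pick_candidate(candidates, 5), 2)
  expect_equal(respsig:::pick_candidate(candidates, 2), 4)
  # all discarded: silhouette alone decides, with a warning
  expect_warning(k <- respsig:::pick_candidate(candidates, 20), "smaller")
  expect_equal(k, 4)
})

test_that("cluster profiles report raw-unit summaries per cluster", {
  delta <- hand_delta(c(1, 1, 3, 5), c(2, 2, 4, 6))
  prof <- cluster_profiles(delta, c(1, 1, 2, 2))
  up <- prof[prof$endpoint == "delta_upper", ]
  expect_equal(up$mean, c(1, 4))
  expect_equal(up$sd, c(0, sqrt(2)))
  expect_equal(up$n, c(2L, 2L))
  expect_error(cluster_profiles(delta, c(1, 2)), "length")
})

test_that("adjusted Rand index matches hand cases and is label-invariant", {
  a <- c(1, 1, 2, 2, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(2, 2, 3, 3, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5,
               tolerance = 1e-12)
  expect_error(adjusted_rand_index(a, a[-1]), "length")
})

test_that("adjusted Rand index agrees with mclust on random labelings", {
  skip_if_not_installed("mclust")
  withr::with_seed(70, {
    for (i in 1:5) {
      a <- sample(1:3, 30, replace = TRUE)
      b <- sample(1:4, 30, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }
  })
})

test_that("Jaccard similarity follows the set formula", {
  expect_equal(jaccard_index(1:3, 1:3), 1)
  expect_equal(jaccard_index(1:3, 4:6), 0)
  expect_equal(jaccard_index(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(jaccard_index(integer(0), 1:2), 0)
  expect_error(jaccard_index(integer(0), integer(0)), "nonempty")
})

test_that("maximum-overlap matching inverts swaps and maximizes total overlap", {
  ref <- c(1, 1, 1, 2, 2)
  swapped <- c(2, 2, 2, 1, 1)
  map <- max_overlap_match(ref, swapped)
  expect_equal(unname(map[c("1", "2")]), c(2L, 1L))
  # contingency [[10, 2], [1, 9]]: identity assignment wins (19 > 3)
  ref2 <- rep(c(1, 2), c(12, 10))
  new2 <- c(rep(1, 10), rep(2, 2), rep(1, 1), rep(2, 9))
  map2 <- max_overlap_match(ref2, new2)
  expect_equal(unname(map2[c("1", "2")]), c(1L, 2L))
  # missing new cluster: the observed one takes its best reference match
  map3 <- max_overlap_match(c(1, 1, 2, 2), c(1, 1, 1, 1))
  expect_equal(unname(map3[["1"]]), 1L)
})

test_that("stability with resampling disabled returns perfect agreement", {
  blobs <- make_blobs(c(6, 8), list(c(0, 0), c(5, 5)), seed = 81)
  delta <- hand_delta(blobs$points[, 1], blobs$points[, 2])
  sol <- find_signatures(delta, k_range = 2:3)
  rep0 <- bootstrap_stability(delta, sol, n_replicates = 20, resample = FALSE)
  expect_equal(rep0$ari_mean, 1)
  expect_equal(rep0$ari_distribution, rep(1, 20))
  expect_equal(rep0$jaccard$mean, rep(1, sol$k))
  expect_equal(rep0$jaccard$sd, rep(0, sol$k))
})

test_that("stability is reproducible and separates structure from noise", {
  blobs <- make_blobs(c(10, 12), list(c(0, 0), c(6, 6)), spread = 0.5,
                      seed = 82)
  d_blob <- hand_delta(blobs$points[, 1], blobs$points[, 2])
  sol_blob <- find_signatures(d_blob, k_range = 2:3)
  s1 <- bootstrap_stability(d_blob, sol_blob, n_replicates = 100, seed = 5)
  s2 <- bootstrap_stability(d_blob, sol_blob, n_replicates = 100, seed = 5)
  expect_identical(s1$ari_distribution, s2$ari_distribution)
  expect_gt(s1$ari_mean, 0.95)
  expect_true(all(s1$jaccard$mean > 0.9))

  noise <- withr::with_seed(83, hand_delta(rnorm(22), rnorm(22)))
  std <- standardize_deltas(noise)
  sol_noise <- list(k = 2, labels = ward_cluster(std$points, 2),
                    scaler = std$scaler)
  s_noise <- bootstrap_stability(noise, sol_noise, n_replicates = 100,
                                 seed = 6)
  expect_lt(s_noise$ari_mean, s1$ari_mean)
  expect_true(all(s1$ari_distribution >= -1 & s1$ari_distribution <= 1))
})

test_that("Pearson chi-square matches hand arithmetic on printed tables", {
  # cluster x group table with rows (0, 3, 9) and (9, 6, 0):
  # 4 + 0.25 + 6.25 + 3.2 + 0.2 + 5 = 18.9
  tab <- rbind(c(0, 3, 9), c(9, 6, 0))
  expect_equal(respsig:::pearson_chi2(tab), 18.9, tolerance = 1e-12)
  expect_equal(respsig:::pearson_chi2(rbind(c(2, 0), c(0, 2))), 4)
  expect_equal(respsig:::pearson_chi2(rbind(c(3, 3), c(3, 3))), 0)
  expect_equal(respsig:::pearson_chi2(tab),
               unname(suppressWarnings(
                 chisq.test(tab, correct = FALSE)$statistic)),
               tolerance = 1e-12)
})

test_that("permutation chi-square association detects the printed configuration", {
  groups <- rep(c("MSTG", "PTG", "CG"), each = 9)
  labels <- c(rep(2, 9), rep(c(1, 2), c(3, 6)), rep(1, 9))
  res <- permutation_chi2(groups, labels, n_perm = 1e5, seed = 4)
  expect_equal(res$chi2, 18.9, tolerance = 1e-12)
  expect_lt(res$p_perm, 0.001)
  # uniform table: statistic zero, p at the top of its range
  res0 <- permutation_chi2(rep(c("A", "B"), 8), rep(c(1, 2), each = 8),
                           n_perm = 500, seed = 7)
  expect_gt(res0$p_perm, 0.5)
  expect_error(permutation_chi2(rep("A", 10), rep(c(1, 2), 5), n_perm = 10),
               "groups")
})
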