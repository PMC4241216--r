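test_that("toy agglomerations follow the linkage definitions", {
  X <- toy1d(0, 1, 10)
  D <- object_distances(X, "euclidean")
  single <- agglomerate(D, "single")
  expect_equal(single$height, c(1, 9))
  average <- agglomerate(D, "average")
  expect_equal(average$height, c(1, 9.5))   # mean of {9, 10}
  complete <- agglomerate(D, "complete")
  expect_equal(complete$height, c(1, 10))
  centroid <- agglomerate(D, "centroid", X = X)
  expect_equal(centroid$height, c(1, 9.5))  # |0.5 - 10|
  ward <- agglomerate(D, "ward", X = X)
  expect_equal(ward$height, c(0.5, (2 * 1 / 3) * 9.5^2))

  two <- agglomerate(object_distances(toy1d(0, 4)), "single")
  expect_equal(two$height, 4)
  expect_equal(two$merge, rbind(c(-1L, -2L)))
  expect_error(agglomerate(stats::dist(toy1d(1)), "single"), "at least 2")
  expect_error(agglomerate(D, "ward"), "require the data matrix")
  expect_warning(
    agglomerate(object_distances(X, "cityblock"), "ward", X = X),
    "Euclidean")
})

test_that("agglomeration matches the brute-force set-formula oracle", {
  for (seed in 1:4) for (m in 3:6) {
    X <- unclass(generate_random_matrix(m, 3, seed * 100 + m))
    D <- object_distances(X, "euclidean")
    for (lk in c("single", "complete", "average", "centroid", "ward")) {
      got <- agglomerate(D, lk, X = X)
      want <- oracle_agglomerate(D, lk, X = X)
      expect_equal(got$height, want$heights, tolerance = 1e-9)
      sets <- step_members_test(got)
      expect_identical(lapply(sets, sort), want$merged)
    }
  }
})

test_that("agglomeration agrees with the reference hierarchical clusterer", {
  set.seed(5)
  X <- matrix(rnorm(9 * 4), 9)
  D <- object_distances(X, "euclidean")
  for (lk in c("single", "complete", "average")) {
    ours <- agglomerate(D, lk)
    ref <- stats::hclust(stats::dist(X), method = lk)
    expect_equal(ours$height, ref$height, tolerance = 1e-9)
    expect_equal(as.matrix(cophenetic_distances(ours)),
                 as.matrix(stats::cophenetic(ref)), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  ## ward: reference heights are sqrt(2 * delta SS)
  ward <- agglomerate(D, "ward", X = X)
  ref <- stats::hclust(stats::dist(X), method = "ward.D2")
  expect_equal(ward$height, ref$height^2 / 2, tolerance = 1e-9)
  ## centroid: reference works on squared distances
  cen <- agglomerate(D, "centroid", X = X)
  ref <- stats::hclust(stats::dist(X)^2, method = "centroid")
  expect_equal(as.matrix(cophenetic_distances(cen)),
               sqrt(as.matrix(stats::cophenetic(ref))), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("monotone linkages produce non-decreasing heights, single is lowest", {
  for (seed in 1:10) {
    X <- unclass(generate_random_matrix(8, 4, seed))
    D <- object_distances(X, "euclidean")
    hs <- agglomerate(D, "single")
    ha <- agglomerate(D, "average")
    hc <- agglomerate(D, "complete")
    for (tr in list(hs, ha, hc)) {
      expect_true(all(diff(tr$height) >= -1e-12))
      expect_false(tr$inversions)
    }
    expect_true(all(hs$height <= ha$height + 1e-9))
    expect_true(all(hs$height <= hc$height + 1e-9))
  }
})

test_that("cophenetic distances read heights off the merge structure", {
  X <- toy1d(0, 1, 10)
  tree <- agglomerate(object_distances(X), "single")
  expect_equal(as.vector(cophenetic_distances(tree)), c(1, 9, 9))
  two <- agglomerate(object_distances(toy1d(0, 4)), "average")
  expect_equal(as.vector(cophenetic_distances(two)), 4)
  ## equilateral configuration: constant cophenetic distances
  eq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  star <- agglomerate(object_distances(eq), "average")
  expect_equal(as.vector(cophenetic_distances(star)), rep(1, 3),
               tolerance = 1e-9)
})

test_that("the cophenetic coefficient follows the product-moment formula", {
  expect_equal(cophenetic_coefficient(c(1, 2, 4), c(1, 2, 4)), 1)
  expect_equal(cophenetic_coefficient(c(1, 10, 9), c(1, 9, 9)), 0.99485,
               tolerance = 1e-4)
  expect_equal(cophenetic_coefficient(c(1, 10, 9), c(1, 9, 9)),
               stats::cor(c(1, 10, 9), c(1, 9, 9)))
  expect_error(cophenetic_coefficient(c(1, 2, 3), c(2, 2, 2)), "degenerate")
  expect_error(cophenetic_coefficient(1, 1), "at least 2")
  expect_error(cophenetic_coefficient(c(1, 2), c(1, 2, 3)), "same length")
})

test_that("the combination scan reproduces per-combination coefficients", {
  X <- standardize(generate_random_matrix(5, 3, 77))
  scan <- scan_combinations(X)
  expect_equal(nrow(scan$table), 15L)
  for (i in seq_len(nrow(scan$table))) {
    D <- object_distances(X, scan$table$metric[i])
    tr <- agglomerate(D, scan$table$linkage[i], X = X,
                      warn_nonmetric = FALSE)
    expect_equal(scan$table$c[i],
                 cophenetic_coefficient(D, cophenetic_distances(tr)))
  }
  best_row <- scan$table[scan$table$metric == scan$best$metric &
                           scan$table$linkage == scan$best$linkage, ]
  expect_equal(best_row$c, max(scan$table$c, na.rm = TRUE))
  ## two objects: every combination is degenerate
  X2 <- matrix(c(-1, 1, -1, 1), 2)
  expect_error(scan_combinations(X2), "degenerate")
})

test_that("flat cuts partition the objects and refine one cluster at a time", {
  X <- unclass(generate_random_matrix(9, 4, 3))
  tree <- agglomerate(object_distances(X), "average")
  expect_equal(cut_tree(tree, 1)$labels, rep(1L, 9), ignore_attr = TRUE)
  expect_equal(cut_tree(tree, 9)$labels, 1:9, ignore_attr = TRUE)
  expect_error(cut_tree(tree, 0), "between 1 and")
  expect_error(cut_tree(tree, 10), "between 1 and")
  for (k in 1:8) {
    a <- cut_tree(tree, k); b <- cut_tree(tree, k + 1)
    expect_equal(sum(lengths(a$members)), 9L)
    ## partition at k+1 refines the one at k by splitting a single cluster
    split_count <- 0
    for (mem in a$members) {
      sub <- unique(b$labels[mem])
      if (length(sub) > 1) split_count <- split_count + 1
      expect_true(all(!sub %in% b$labels[-mem]))
    }
    expect_equal(split_count, 1L)
  }
  ## dendrogram-style numbering: singletons keep leaf ids, groups get m+step
  cut2 <- cut_tree(tree, 9)
  expect_equal(cut2$node_ids, 1:9)
  expect_equal(cut_tree(tree, 1)$node_ids, 9L + 8L)
})
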