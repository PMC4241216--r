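fixture_stages <- function(k = 4) {
  X <- standardize(table3_fixture())
  scan <- scan_combinations(X)
  profile <- validity_profile(scan$tree, X)
  pca <- fit_pca(X)
  view <- embed_tree(scan$tree, pca, k)
  list(X = X, scan = scan, profile = profile, pca = pca, view = view)
}

test_that("internal nodes sit at the centre of gravity of their leaves", {
  X <- standardize(generate_random_matrix(9, 5, 41))
  tree <- agglomerate(object_distances(X), "average")
  pca <- fit_pca(X)
  view <- embed_tree(tree, pca, 3)
  sets <- step_members_test(tree)
  for (t in seq_along(sets)) {
    nd <- view$nodes[9 + t, ]
    expect_equal(nd$x, mean(pca$psi[sets[[t]], 1]), tolerance = 1e-9)
    expect_equal(nd$y, mean(pca$psi[sets[[t]], 2]), tolerance = 1e-9)
    expect_equal(nd$height, tree$height[t])
  }
  expect_equal(view$nodes$x[1:9], unname(pca$psi[, 1]))
  expect_equal(nrow(view$segments), 2 * (9 - 1))
})

test_that("two objects embed as a single apex at their midpoint", {
  X <- standardize(rbind(c(0, 1), c(4, 3)))
  tree <- agglomerate(object_distances(X), "average")
  pca <- fit_pca(X)
  view <- embed_tree(tree, pca, 1)
  apex <- view$nodes[3, ]
  expect_equal(apex$x, mean(pca$psi[, 1]))
  expect_equal(apex$y, mean(pca$psi[, 2]))
  expect_equal(apex$height, tree$height[1])
})

test_that("the embedded geometry is invariant to object order", {
  A <- unclass(generate_random_matrix(8, 4, 55))
  rownames(A) <- paste0("o", 1:8)
  run <- function(M) {
    X <- standardize(M)
    tree <- agglomerate(object_distances(X), "average")
    embed_tree(tree, fit_pca(X), 3)
  }
  v1 <- run(A)
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  v2 <- run(A[perm, ])
  ## leaf coordinates agree per label, up to the per-axis sign convention
  ord2 <- match(v1$labels, v2$labels)
  for (ax in c("x", "y")) {
    a <- v1$nodes[[ax]][1:8]; b <- v2$nodes[[ax]][ord2]
    expect_true(isTRUE(all.equal(a, b, tolerance = 1e-9)) ||
                  isTRUE(all.equal(a, -b, tolerance = 1e-9)))
  }
  ## merge heights and cluster composition agree
  expect_equal(sort(v1$nodes$height), sort(v2$nodes$height),
               tolerance = 1e-9)
  mem1 <- lapply(v1$cut$members, function(ix) sort(v1$labels[ix]))
  mem2 <- lapply(v2$cut$members, function(ix) sort(v2$labels[ix]))
  expect_true(all(vapply(mem1, function(s)
    any(vapply(mem2, identical, TRUE, y = s)), TRUE)))

  pca_other <- fit_pca(standardize(generate_random_matrix(5, 4, 1)))
  tree <- agglomerate(object_distances(standardize(A)), "average")
  expect_error(embed_tree(tree, pca_other, 2), "same objects")
})

test_that("the interpretation report integrates all stages consistently", {
  st <- fixture_stages()
  rep <- interpretation_report(st$scan, st$profile, st$pca, st$view)
  ## report echoes the scan winner and the cut labels
  expect_equal(rep$best_combination$c,
               max(st$scan$table$c, na.rm = TRUE))
  expect_equal(lapply(rep$clusters, `[[`, "objects"),
               lapply(st$view$cut$members,
                      function(ix) st$view$labels[ix]))
  expect_equal(rep$suggested_k, suggest_k(st$profile))
  expect_equal(rep$kaiser, kaiser_count(st$pca), ignore_attr = TRUE)
  expect_true(all(c("best_combination", "validity", "clusters", "axes",
                    "correlation_circle", "axis1_groups")
                  %in% names(rep)))
  ## top contributors exceed the uniform share
  for (ax in rep$axes) {
    ci <- ctr_individuals(st$pca, ax$axis)
    expect_true(all(ci[ax$top_objects] > 1 / st$pca$m))
  }
  expect_error(interpretation_report(st$scan, st$profile, st$pca),
               "missing")
})

test_that("a tiny three-object analysis reports every section", {
  X <- standardize(generate_random_matrix(3, 2, 8))
  scan <- scan_combinations(X)
  profile <- validity_profile(scan$tree, X)
  pca <- fit_pca(X)
  view <- embed_tree(scan$tree, pca, 2)
  rep <- interpretation_report(scan, profile, pca, view)
  expect_length(rep$clusters, 2L)
  expect_s3_class(rep, "variability_report")
})

test_that("report serialization is deterministic", {
  st <- fixture_stages()
  rep <- interpretation_report(st$scan, st$profile, st$pca, st$view)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_report(rep, f1); write_report(rep, f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile(fileext = ".md")
  write_report(rep, f3, "markdown")
  expect_gt(length(readLines(f3)), 5)
})
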