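## Independent oracle implementations and shared fixtures for the tests.
## The oracles deliberately use different formulations from the package
## (set formulas instead of Lance-Williams updates, additive between-group
## sums of squares instead of subtraction) so that agreement is meaningful.

popsd <- function(v) sqrt(mean((v - mean(v))^2))

toy1d <- function(...) matrix(c(...), ncol = 1)

## brute-force agglomeration straight from the set definitions of the
## five linkage criteria
oracle_agglomerate <- function(D, linkage, X = NULL) {
  Dm <- as.matrix(D)
  m <- nrow(Dm)
  clusters <- as.list(seq_len(m))
  heights <- numeric(0)
  merged <- list()
  crit <- function(a, b) {
    pair <- Dm[a, b, drop = FALSE]
    switch(linkage,
      single = min(pair),
      complete = max(pair),
      average = mean(pair),
      centroid = sqrt(sum((colMeans(X[a, , drop = FALSE]) -
                             colMeans(X[b, , drop = FALSE]))^2)),
      ward = {
        d <- sqrt(sum((colMeans(X[a, , drop = FALSE]) -
                         colMeans(X[b, , drop = FALSE]))^2))
        length(a) * length(b) / (length(a) + length(b)) * d^2
      })
  }
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)[-length(clusters)])
      for (j in (i + 1L):length(clusters)) {
        v <- crit(clusters[[i]], clusters[[j]])
        key <- c(min(min(clusters[[i]]), min(clusters[[j]])),
                 max(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || v < best$v - 1e-15 ||
            (abs(v - best$v) <= 1e-15 &&
               (key[1] < best$key[1] ||
                  (key[1] == best$key[1] && key[2] < best$key[2]))))
          best <- list(v = v, i = i, j = j, key = key)
      }
    heights <- c(heights, best$v)
    merged <- c(merged, list(sort(c(clusters[[best$i]],
                                    clusters[[best$j]]))))
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  list(heights = heights, merged = merged)
}

## between-group additive sums-of-squares oracle for the validity indices
oracle_rsq_pf <- function(X, labels) {
  X <- as.matrix(X)
  grand <- colMeans(X)
  groups <- split(seq_len(nrow(X)), labels)
  ssb <- sum(vapply(groups, function(ix)
    length(ix) * sum((colMeans(X[ix, , drop = FALSE]) - grand)^2),
    numeric(1)))
  sst <- sum(sweep(X, 2, grand)^2)
  k <- length(groups); m <- nrow(X)
  list(rsq = ssb / sst,
       pf = if (k > 1 && k < m) (ssb / (k - 1)) / ((sst - ssb) / (m - k))
            else NA_real_)
}

## small nested area configurations for generator-driven tests; indices
## must equal positions, cost areas paired with their quantity area
make_areas <- function(categories) {
  nq <- length(categories)
  c(lapply(seq_len(nq), function(i) list(
      index = i, label = paste0("Q. ", names(categories)[i]),
      kind = "quantity", category = names(categories)[i],
      factors = categories[[i]], aggregation = "sum_then_mean",
      paired = NA_integer_)),
    lapply(seq_len(nq), function(i) list(
      index = nq + i, label = paste0("C. ", names(categories)[i]),
      kind = "unit_cost", category = names(categories)[i],
      factors = categories[[i]],
      aggregation = if (length(categories[[i]]) > 1L) "mean_cost_if_used"
                    else "direct_if_used",
      paired = i)))
}

## planted-structure scenario: a resource-heavy treatment block whose drug
## unit costs diverge strongly between countries, and a follow-up block
## with country-identical imaging; the natural 4-group structure is
## (treatment x country) + (light/heavy follow-up, countries pooled)
planted_scenario <- function(seed) {
  areas <- make_areas(list(hosp = "days", drugs = "drug", imaging = "scan"))
  phases <- c("treatment A", "treatment B",
              "follow-up light", "follow-up heavy")
  objects <- management_objects(phases, c("France", "Italy"))
  means <- do.call(rbind, lapply(c("France", "Italy"), function(co)
    do.call(rbind, lapply(phases, function(ph) {
      trt <- grepl("treatment", ph)
      data.frame(country = co, phase = ph,
                 factor = c("days", "drug", "scan"),
                 mean = c(if (trt) 15 else 0, if (trt) 3 else 0,
                          if (trt) 0 else if (ph == "follow-up heavy") 10
                          else 1),
                 family = "poisson", stringsAsFactors = FALSE)
    }))))
  costs <- data.frame(country = rep(c("France", "Italy"), each = 3),
                      factor = rep(c("days", "drug", "scan"), 2),
                      unit_cost = c(500, 4000, 80, 480, 200, 80))
  list(config = generator_config(
         patients = c(France = 150L, Italy = 150L),
         relapse_prob = c(France = 0, Italy = 0),
         means = means, costs = costs,
         year_offset = stats::setNames(rep(0L, 4), phases),
         seed = seed, areas = areas),
       objects = objects, areas = areas,
       planted = c(1, 2, 1, 2, 3, 3, 4, 4))
}

planted_ari <- function(seed) {
  sc <- planted_scenario(seed)
  g <- generate_patients(sc$config)
  A <- build_matrix(g$records, g$costs, objects = sc$objects,
                    areas = sc$areas)
  X <- standardize(A)
  tree <- agglomerate(object_distances(X, "euclidean"), "average")
  mclust::adjustedRandIndex(cut_tree(tree, 4)$labels, sc$planted)
}

## reconstruct each merge step's member set from the hclust-coded matrix
step_members_test <- function(tree) {
  sets <- vector("list", tree$m - 1L)
  for (t in seq_len(tree$m - 1L))
    sets[[t]] <- sort(unlist(lapply(tree$merge[t, ], function(code)
      if (code < 0) -code else sets[[code]])))
  sets
}
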