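#' Agglomerative hierarchical clustering of management objects
#'
#' Builds the hierarchical tree by iteratively merging the pair of clusters
#' with the smallest inter-cluster criterion, starting from singletons, under
#' one of five linkage criteria:
#' \describe{
#'   \item{`single`}{smallest pairwise object distance between the groups;}
#'   \item{`complete`}{largest pairwise object distance;}
#'   \item{`average`}{mean of all pairwise object distances (UPGMA);}
#'   \item{`centroid`}{distance between the group centroids
#'     \eqn{d(\bar x_r, \bar x_s)};}
#'   \item{`ward`}{incremental sum of squares
#'     \eqn{\frac{n_r n_s}{n_r + n_s} d^2(\bar x_r, \bar x_s)}.}
#' }
#' Single, complete and average linkage are driven by Lance-Williams updates
#' of the pairwise distances; centroid and Ward recompute centroid distances
#' at every step, in the same metric as `D`, which requires the data matrix
#' `X`.  Centroid and Ward are defined for Euclidean geometry; requesting
#' them with another metric triggers a warning but is computed anyway so
#' that a full metric-by-linkage scan remains possible.
#'
#' When two candidate merges attain exactly the minimal criterion, the pair
#' whose (smallest leaf index, largest leaf index) key is lexicographically
#' smallest is merged, making the procedure deterministic.
#'
#' @param D A distance object from [object_distances()] (any `dist` works;
#'   the metric tag defaults to `"euclidean"`).
#' @param linkage One of `"single"`, `"complete"`, `"average"`, `"centroid"`,
#'   `"ward"`.
#' @param X The data matrix the distances were computed from; required for
#'   centroid and Ward linkage.
#' @param warn_nonmetric Emit the centroid/Ward non-Euclidean warning.
#' @return A `merge_tree`: a list with `merge` (the (m-1) x 2 step matrix in
#'   [stats::hclust()] coding), `height`, `sizes` (size of each newly formed
#'   cluster), `linkage`, `metric`, `labels`, `m`, and `inversions` (TRUE if
#'   any merge height decreases, possible for centroid linkage).
#' @seealso [cut_tree()], [cophenetic_distances()], [scan_combinations()]
#' @export
agglomerate <- function(D, linkage = c("single", "complete", "average",
                                       "centroid", "ward"),
                        X = NULL, warn_nonmetric = TRUE) {
  linkage <- match.arg(linkage)
  metric <- attr(D, "metric")
  if (is.null(metric)) metric <- "euclidean"
  Dm <- as.matrix(D)
  m <- nrow(Dm)
  if (m < 2L) stop("at least 2 objects are required", call. = FALSE)
  labels <- attr(D, "Labels")
  if (is.null(labels)) labels <- as.character(seq_len(m))
  geometric <- linkage %in% c("centroid", "ward")
  if (geometric) {
    if (is.null(X))
      stop("centroid and Ward linkage require the data matrix 'X'",
           call. = FALSE)
    X <- unclass(as.matrix(X))
    if (nrow(X) != m) stop("'X' and 'D' disagree on the number of objects",
                           call. = FALSE)
    if (metric != "euclidean" && warn_nonmetric)
      warning(linkage, " linkage is defined for Euclidean geometry; ",
              "computing with metric '", metric, "' anyway", call. = FALSE)
  }
  cov_inverse <- attr(D, "cov_inverse")

  ## working criterion between active clusters
  W <- switch(linkage, ward = Dm^2 / 2, Dm)
  diag(W) <- Inf
  members <- as.list(seq_len(m))   # leaf index sets per slot
  sizes <- rep(1L, m)
  codes <- -seq_len(m)             # hclust coding: -leaf or +step
  active <- rep(TRUE, m)

  merge <- matrix(0L, m - 1L, 2L)
  height <- numeric(m - 1L)
  new_sizes <- integer(m - 1L)

  for (step in seq_len(m - 1L)) {
    Wa <- W
    Wa[!active, ] <- Inf
    Wa[, !active] <- Inf
    cmin <- min(Wa)
    cand <- which(Wa == cmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ## lexicographic tie-break on (min leaf, max leaf) of the joined set
    key_small <- pmin(vapply(members[cand[, 1]], min, 0L),
                      vapply(members[cand[, 2]], min, 0L))
    key_large <- pmax(vapply(members[cand[, 1]], min, 0L),
                      vapply(members[cand[, 2]], min, 0L))
    pick <- order(key_small, key_large)[1L]
    r <- cand[pick, 1L]; s <- cand[pick, 2L]

    merge[step, ] <- sort_pair(codes[r], codes[s])
    height[step] <- cmin
    nr <- sizes[r]; ns <- sizes[s]
    new_sizes[step] <- nr + ns

    ## merged cluster occupies slot r
    members[[r]] <- c(members[[r]], members[[s]])
    sizes[r] <- nr + ns
    codes[r] <- step
    active[s] <- FALSE

    others <- which(active & seq_len(m) != r)
    if (length(others)) {
      if (geometric) {
        cen_r <- colMeans(X[members[[r]], , drop = FALSE])
        for (t in others) {
          cen_t <- colMeans(X[members[[t]], , drop = FALSE])
          cd <- point_distance(cen_r, cen_t, metric, cov_inverse)
          W[r, t] <- W[t, r] <-
            if (linkage == "ward") sizes[r] * sizes[t] /
              (sizes[r] + sizes[t]) * cd^2 else cd
        }
      } else {
        upd <- switch(linkage,
          single   = pmin(W[r, others], W[s, others]),
          complete = pmax(W[r, others], W[s, others]),
          average  = (nr * W[r, others] + ns * W[s, others]) / (nr + ns))
        W[r, others] <- W[others, r] <- upd
      }
    }
    W[s, ] <- W[, s] <- Inf
  }
  structure(list(merge = merge, height = height, sizes = new_sizes,
                 linkage = linkage, metric = metric, labels = labels, m = m,
                 inversions = any(diff(height) < -1e-12)),
            class = "merge_tree")
}

sort_pair <- function(a, b) {
  ## hclust convention: leaves by ascending index, then clusters by step;
  ## in a mixed pair the leaf (negative code) comes first
  if (a < 0 && b < 0) c(max(a, b), min(a, b)) else c(min(a, b), max(a, b))
}

## leaf index sets of every internal node (step), in merge order
step_members <- function(tree) {
  sets <- vector("list", tree$m - 1L)
  for (t in seq_len(tree$m - 1L)) {
    sets[[t]] <- unlist(lapply(tree$merge[t, ], function(code)
      if (code < 0) -code else sets[[code]]))
  }
  sets
}

#' @export
print.merge_tree <- function(x, ...) {
  cat("Agglomerative merge tree: ", x$m, " objects, linkage = ", x$linkage,
      ", metric = ", x$metric, "\n", sep = "")
  if (x$inversions) cat("  (contains height inversions)\n")
  df <- data.frame(step = seq_len(x$m - 1L), node = x$m + seq_len(x$m - 1L),
                   left = x$merge[, 1], right = x$merge[, 2],
                   height = signif(x$height, 6), size = x$sizes)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.hclust.merge_tree <- function(x, ...) {
  ord <- integer(0)
  expand <- function(code) {
    if (code < 0) return(-code)
    c(expand(x$merge[code, 1]), expand(x$merge[code, 2]))
  }
  ord <- expand(x$m - 1L)
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels,
                 method = x$linkage, dist.method = x$metric,
                 call = match.call()),
            class = "hclust")
}

#' Cophenetic distances of a merge tree
#'
#' The cophenetic distance between two objects is the height of the lowest
#' tree node that joins them.
#'
#' @param tree A `merge_tree` from [agglomerate()].
#' @return A [stats::dist] object of cophenetic distances.
#' @export
cophenetic_distances <- function(tree) {
  m <- tree$m
  Z <- matrix(0, m, m)
  sets <- vector("list", 2L * m - 1L)
  sets[seq_len(m)] <- as.list(seq_len(m))
  for (t in seq_len(m - 1L)) {
    ids <- ifelse(tree$merge[t, ] < 0, -tree$merge[t, ], tree$merge[t, ] + m)
    left <- sets[[ids[1]]]; right <- sets[[ids[2]]]
    Z[left, right] <- Z[right, left] <- tree$height[t]
    sets[[m + t]] <- c(left, right)
  }
  out <- stats::as.dist(Z)
  attr(out, "Labels") <- tree$labels
  out
}

#' Cophenetic correlation coefficient
#'
#' Product-moment agreement between the original pairwise distances `Y` and
#' the cophenetic distances `Z` induced by a tree,
#' \deqn{c = \frac{\sum_{i<j}(Y_{ij}-\bar y)(Z_{ij}-\bar z)}
#'   {\sqrt{\sum_{i<j}(Y_{ij}-\bar y)^2 \sum_{i<j}(Z_{ij}-\bar z)^2}}.}
#' The closer `c` is to 1, the more faithfully the tree preserves the
#' original distances.
#'
#' @param Y,Z Condensed distance vectors (or `dist` objects) of equal length.
#' @return The coefficient, in `[-1, 1]`.
#' @export
cophenetic_coefficient <- function(Y, Z) {
  y <- as.vector(Y); z <- as.vector(Z)
  if (length(y) != length(z))
    stop("'Y' and 'Z' must have the same length", call. = FALSE)
  if (length(y) < 2L)
    stop("at least 2 distance pairs are required", call. = FALSE)
  dy <- y - mean(y); dz <- z - mean(z)
  deny <- sum(dy^2); denz <- sum(dz^2)
  if (deny == 0 || denz == 0)
    stop("degenerate input: constant distances have no cophenetic correlation",
         call. = FALSE)
  sum(dy * dz) / sqrt(deny * denz)
}

#' Scan all metric-by-linkage combinations
#'
#' Computes the cophenetic correlation coefficient for every combination of
#' the three distance metrics and five linkage criteria (15 pairs) and
#' selects the pair with the highest coefficient as the clustering model.
#' Degenerate combinations (e.g. constant cophenetic distances) are recorded
#' as `NA` rather than aborting the scan.
#'
#' @param X A `standardized_matrix`.
#' @param metrics,linkages Subsets of metrics/linkages to scan.
#' @return A `combination_scan`: list with `table` (data frame of `metric`,
#'   `linkage`, `c`), `best` (list `metric`, `linkage`, `c`), and `tree`
#'   (the winning `merge_tree`).
#' @export
scan_combinations <- function(X,
                              metrics = c("euclidean", "mahalanobis",
                                          "cityblock"),
                              linkages = c("single", "complete", "average",
                                           "centroid", "ward")) {
  grid <- expand.grid(linkage = linkages, metric = metrics,
                      stringsAsFactors = FALSE)[, 2:1]
  cvals <- rep(NA_real_, nrow(grid))
  for (mt in metrics) {
    D <- object_distances(X, mt)
    for (lk in linkages) {
      i <- which(grid$metric == mt & grid$linkage == lk)
      cvals[i] <- tryCatch({
        tr <- agglomerate(D, lk, X = X, warn_nonmetric = FALSE)
        cophenetic_coefficient(D, cophenetic_distances(tr))
      }, error = function(e) NA_real_)
    }
  }
  if (all(is.na(cvals)))
    stop("all metric-linkage combinations are degenerate", call. = FALSE)
  ib <- which.max(cvals)
  best <- list(metric = grid$metric[ib], linkage = grid$linkage[ib],
               c = cvals[ib])
  tree <- agglomerate(object_distances(X, best$metric), best$linkage, X = X,
                      warn_nonmetric = FALSE)
  structure(list(table = cbind(grid, c = cvals), best = best, tree = tree),
            class = "combination_scan")
}

#' @export
print.combination_scan <- function(x, ...) {
  cat("Cophenetic correlation scan (", nrow(x$table), " combinations)\n",
      sep = "")
  tab <- x$table
  tab$c <- round(tab$c, 5)
  print(tab, row.names = FALSE)
  cat("best pair: (", x$best$linkage, ", ", x$best$metric, "), c = ",
      format(x$best$c, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Cut a merge tree into k clusters
#'
#' Removes the k-1 last (highest, for monotone linkages) merges, i.e. stops
#' the agglomeration after m-k steps, and returns the flat partition.
#' Clusters are labelled 1..k in order of their smallest member.  Each
#' cluster also receives the dendrogram-style node number: leaves are
#' numbered 1..m and internal nodes m+1..2m-1 in merge order, so a
#' non-singleton cluster is identified by the node at which it was completed.
#'
#' @param tree A `merge_tree`.
#' @param k Number of clusters, between 1 and m.
#' @return A list with `labels` (integer vector per object), `members`
#'   (list of leaf index vectors per cluster) and `node_ids` (dendrogram
#'   node number per cluster).
#' @export
cut_tree <- function(tree, k) {
  m <- tree$m
  if (length(k) != 1L || is.na(k) || k < 1L || k > m)
    stop("'k' must be an integer between 1 and ", m, call. = FALSE)
  k <- as.integer(k)
  sets <- as.list(seq_len(m))          # keyed by node id 1..2m-1
  node <- seq_len(m)                   # current node id per active cluster
  active <- as.list(seq_len(m))        # active cluster -> node id
  for (t in seq_len(m - k)) {
    ids <- ifelse(tree$merge[t, ] < 0, -tree$merge[t, ], tree$merge[t, ] + m)
    sets[[m + t]] <- c(sets[[ids[1]]], sets[[ids[2]]])
    active <- active[!vapply(active, identical, TRUE, y = ids[[1]])]
    active <- active[!vapply(active, identical, TRUE, y = ids[[2]])]
    active <- c(active, m + t)
  }
  node_ids <- unlist(active)
  members <- sets[node_ids]
  ord <- order(vapply(members, min, 0L))
  members <- members[ord]
  node_ids <- node_ids[ord]
  labels <- integer(m)
  for (i in seq_along(members)) labels[members[[i]]] <- i
  names(labels) <- tree$labels
  list(labels = labels, members = members, node_ids = node_ids)
}
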