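## pooled within-cluster sum of squares over all variables
ss_within <- function(X, members) {
  sub <- X[members, , drop = FALSE]
  sum(sweep(sub, 2, colMeans(sub))^2)
}

ss_total <- function(X) sum(sweep(X, 2, colMeans(X))^2)

check_labels <- function(X, labels) {
  if (length(labels) != nrow(X))
    stop("'labels' must assign every row of 'X' to a cluster", call. = FALSE)
  if (length(labels) == 0L || anyNA(labels))
    stop("empty or missing cluster labels", call. = FALSE)
  split(seq_len(nrow(X)), labels)
}

#' R-squared of a flat partition
#'
#' `RSQ = 1 - SSW/SST`: the share of the total dispersion of the
#' standardized cloud explained by the between-cluster separation.  High
#' values mean heterogeneous (well separated) clusters; `RSQ` is 0 for a
#' single cluster and 1 for all-singleton partitions.
#'
#' @param X A `standardized_matrix` (any numeric matrix works).
#' @param labels Cluster assignment per row.
#' @return RSQ in `[0, 1]`.
#' @export
rsq <- function(X, labels) {
  X <- unclass(as.matrix(X))
  groups <- check_labels(X, labels)
  ssw <- sum(vapply(groups, function(ix) ss_within(X, ix), numeric(1)))
  1 - ssw / ss_total(X)
}

#' Semi-partial R-squared of one merge
#'
#' The loss of within-cluster homogeneity caused by a single agglomeration
#' step, as a share of the total dispersion:
#' `SPRSQ = (SSW(merged) - SSW(left) - SSW(right)) / SST`.  Summed over all
#' m-1 merges it telescopes to 1.
#'
#' @param X The data matrix the tree was built on.
#' @param tree A `merge_tree`.
#' @param step Merge step (1 to m-1).
#' @return The SPRSQ of that step.
#' @export
sprsq <- function(X, tree, step) {
  X <- unclass(as.matrix(X))
  if (step < 1L || step > tree$m - 1L)
    stop("'step' out of range", call. = FALSE)
  sets <- step_members(tree)
  children <- lapply(tree$merge[step, ], function(code)
    if (code < 0) -code else sets[[code]])
  (ss_within(X, sets[[step]]) -
     ss_within(X, children[[1]]) - ss_within(X, children[[2]])) / ss_total(X)
}

#' Root-mean-square standard deviation of a cluster
#'
#' Pooled-variance compactness of one cluster:
#' `sqrt(SSW / (n_vars * (size - 1)))`, with the convention that singletons
#' have RMSSTD 0.  Small values indicate a homogeneous cluster.
#'
#' @param X The data matrix.
#' @param members Row indices of the cluster.
#' @return The RMSSTD.
#' @export
rmsstd <- function(X, members) {
  X <- unclass(as.matrix(X))
  if (length(members) < 1L) stop("empty cluster", call. = FALSE)
  if (length(members) == 1L) return(0)
  sqrt(ss_within(X, members) / (ncol(X) * (length(members) - 1L)))
}

#' Pseudo-F statistic of a flat partition
#'
#' The Calinski-Harabasz ratio of between- to within-cluster mean squares,
#' `pF = (SSB/(k-1)) / (SSW/(m-k))`, computed on the space the clusters were
#' formed in.  Peaks over k indicate candidate cluster numbers.  Perfectly
#' separated duplicate points give `SSW = 0`, reported as `Inf`.
#'
#' @inheritParams rsq
#' @return The pseudo-F value (possibly `Inf`).
#' @export
pseudo_f <- function(X, labels) {
  X <- unclass(as.matrix(X))
  groups <- check_labels(X, labels)
  k <- length(groups); m <- nrow(X)
  if (k < 2L || k >= m)
    stop("pseudo-F requires 2 <= k < m", call. = FALSE)
  ssw <- sum(vapply(groups, function(ix) ss_within(X, ix), numeric(1)))
  ssb <- ss_total(X) - ssw
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (m - k))
}

#' Cluster-number validity profile of a merge tree
#'
#' Evaluates, for every candidate number of clusters k, the four
#' sums-of-squares indices used jointly to choose the partition: RSQ of the
#' k-cluster cut, SPRSQ of the merge that produced k clusters, RMSSTD of the
#' cluster formed by that merge, and the pseudo-F statistic (plus its
#' max-normalized version `pseudo_f_scaled` in `[0, 1]` for joint display).
#'
#' @param tree A `merge_tree`.
#' @param X The matrix the tree was built on.
#' @param k_range Candidate cluster numbers; defaults to `2:(m-1)`.
#' @return A `validity_profile` data frame with columns `k`, `rsq`, `sprsq`,
#'   `rmsstd`, `pseudo_f`, `pseudo_f_scaled`, and attribute `suggested_k`.
#' @export
validity_profile <- function(tree, X, k_range = NULL) {
  X <- unclass(as.matrix(X))
  m <- tree$m
  if (is.null(k_range)) k_range <- seq(2L, m - 1L)
  if (any(k_range < 2L | k_range > m - 1L))
    stop("'k_range' must lie within [2, m-1]", call. = FALSE)
  sets <- step_members(tree)
  rows <- lapply(k_range, function(k) {
    cut <- cut_tree(tree, k)
    step <- m - k  # the merge that reduced k+1 clusters to k
    data.frame(k = k,
               rsq = rsq(X, cut$labels),
               sprsq = sprsq(X, tree, step),
               rmsstd = rmsstd(X, sets[[step]]),
               pseudo_f = pseudo_f(X, cut$labels))
  })
  out <- do.call(rbind, rows)
  fin <- out$pseudo_f[is.finite(out$pseudo_f)]
  out$pseudo_f_scaled <- if (length(fin) && max(fin) > 0)
    pmin(out$pseudo_f / max(fin), 1) else rep(NA_real_, nrow(out))
  class(out) <- c("validity_profile", "data.frame")
  attr(out, "suggested_k") <- out$k[which.max(out$pseudo_f)]
  out
}

#' Suggested number of clusters from a validity profile
#'
#' The pseudo-F statistic is used as the decisive index: the suggested k is
#' the location of its maximum over the profile, with ties broken toward the
#' smaller k.  The other three indices are reported for joint inspection.
#'
#' @param profile A `validity_profile`.
#' @return The suggested integer k.
#' @export
suggest_k <- function(profile) {
  as.integer(profile$k[which.max(profile$pseudo_f)])
}

#' @export
print.validity_profile <- function(x, ...) {
  cat("Cluster-number validity profile (suggested k = ",
      attr(x, "suggested_k"), ")\n", sep = "")
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], signif, digits = 5)
  print(y, row.names = FALSE)
  invisible(x)
}
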