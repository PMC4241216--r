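#' Principal component analysis of the standardized variability matrix
#'
#' Diagonalizes the correlation matrix `Gamma = (1/m) X'X` of the
#' column-standardized object-by-area matrix.  With the population
#' standardization, `Gamma` has unit diagonal, so the eigenvalues live on
#' the correlation scale (they sum to the number of areas n) and Kaiser's
#' "eigenvalue above 1" retention rule is meaningful.
#'
#' Quantities produced, in the conventional French-school notation:
#' \itemize{
#'   \item eigenvalues \eqn{\lambda_\alpha} (descending) with inertia
#'     proportions and cumulative proportions;
#'   \item individual (object) coordinates \eqn{\psi_\alpha = X u_\alpha};
#'   \item variable (area) coordinates
#'     \eqn{\phi_\alpha(j) = \sqrt{\lambda_\alpha}\, u_\alpha(j)}, which
#'     equal the correlation between area j and the factor
#'     \eqn{\psi_\alpha};
#'   \item contributions \eqn{CTR_\alpha(i)}, \eqn{CTR_\alpha(j)} and
#'     representation qualities \eqn{\cos^2_\alpha(j)}.
#' }
#' Eigenvector signs are fixed so that the loading of largest magnitude on
#' each axis is positive; axis orientations are therefore deterministic but
#' may be mirrored relative to other software.
#'
#' @param X A `standardized_matrix` (population column standardization).
#' @param check Verify that `X` is standardized (mean 0, population sd 1 per
#'   column) and error otherwise.
#' @return A `cost_pca` object: list with `eigenvalues`, `proportions`,
#'   `cum_proportions`, `psi` (m x n individual coordinates), `phi` (n x n
#'   variable coordinates), `loadings` (eigenvectors `u`), `m`, `n`,
#'   `row_labels`, `col_labels`.
#' @export
fit_pca <- function(X, check = TRUE) {
  Xm <- unclass(as.matrix(X))
  if (check && !is_standardized(Xm))
    stop("'X' must be column-standardized (mean 0, population sd 1); ",
         "use standardize()", call. = FALSE)
  m <- nrow(Xm); n <- ncol(Xm)
  if (is.null(rownames(Xm))) rownames(Xm) <- as.character(seq_len(m))
  if (is.null(colnames(Xm))) colnames(Xm) <- paste0("V", seq_len(n))
  G <- crossprod(Xm) / m
  e <- eigen(G, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  U <- e$vectors
  ## deterministic sign: largest-|loading| coefficient positive per axis
  for (a in seq_len(n)) {
    i <- which.max(abs(U[, a]))
    if (U[i, a] < 0) U[, a] <- -U[, a]
  }
  psi <- Xm %*% U
  phi <- U %*% diag(sqrt(lambda), n)
  ax <- paste0("F", seq_len(n))
  dimnames(psi) <- list(rownames(Xm), ax)
  dimnames(phi) <- list(colnames(Xm), ax)
  dimnames(U) <- list(colnames(Xm), ax)
  structure(list(eigenvalues = lambda,
                 proportions = lambda / sum(lambda),
                 cum_proportions = cumsum(lambda) / sum(lambda),
                 psi = psi, phi = phi, loadings = U,
                 m = m, n = n,
                 row_labels = rownames(Xm), col_labels = colnames(Xm)),
            class = "cost_pca")
}

#' @export
print.cost_pca <- function(x, ...) {
  cat("PCA of a ", x$m, " x ", x$n, " standardized variability matrix\n",
      sep = "")
  df <- data.frame(axis = seq_len(x$n),
                   eigenvalue = signif(x$eigenvalues, 5),
                   proportion = round(100 * x$proportions, 2),
                   cumulative = round(100 * x$cum_proportions, 2))
  print(utils::head(df, 8), row.names = FALSE)
  cat("eigenvalues > 1 (Kaiser): ", kaiser_count(x), "\n", sep = "")
  invisible(x)
}

check_axis <- function(pca, axis) {
  if (axis < 1L || axis > pca$n) stop("'axis' out of range", call. = FALSE)
  if (pca$eigenvalues[axis] <= 1e-12)
    stop("axis ", axis, " carries no inertia", call. = FALSE)
  axis
}

#' Contributions of objects to a principal axis
#'
#' `CTR_alpha(i) = psi_alpha(i)^2 / sum_i psi_alpha(i)^2`; objects with a
#' contribution above the uniform share 1/m drive the axis.
#'
#' @param pca A `cost_pca`.
#' @param axis Axis number.
#' @return Named numeric vector of shares summing to 1.
#' @export
ctr_individuals <- function(pca, axis) {
  check_axis(pca, axis)
  v <- pca$psi[, axis]^2
  stats::setNames(v / sum(v), pca$row_labels)
}

#' Contributions of areas to a principal axis
#'
#' `CTR_alpha(j) = phi_alpha(j)^2 / sum_j phi_alpha(j)^2`.
#'
#' @inheritParams ctr_individuals
#' @return Named numeric vector of shares summing to 1.
#' @export
ctr_variables <- function(pca, axis) {
  check_axis(pca, axis)
  v <- pca$phi[, axis]^2
  stats::setNames(v / sum(v), pca$col_labels)
}

#' Representation quality of areas on a principal axis
#'
#' `cos2_alpha(j) = phi_alpha(j)^2 / ||x_j||^2`.  On the correlation scale
#' the squared norm of every standardized area is 1, so the qualities of one
#' area sum to 1 over all axes.
#'
#' @inheritParams ctr_individuals
#' @return Named numeric vector in `[0, 1]`.
#' @export
cos2_variables <- function(pca, axis) {
  check_axis(pca, axis)
  norms2 <- rowSums(pca$phi^2)   # = diag(Gamma) = 1 on the correlation scale
  stats::setNames(pca$phi[, axis]^2 / norms2, pca$col_labels)
}

#' Correlation-circle summary of the first factorial plane
#'
#' For every area, the coordinates on the first two axes, the distance from
#' the origin \eqn{r_j = \sqrt{\phi_1^2(j) + \phi_2^2(j)}} and a flag for
#' areas close enough to the unit circle (`r_j >= radius`) to be
#' interpretable on the plane.  Areas are sorted by descending `r_j`.
#'
#' @param pca A `cost_pca` with rank at least 2.
#' @param radius Interpretability threshold (the conventional inner circle
#'   of radius 0.8).
#' @return A data frame with columns `area`, `phi1`, `phi2`, `r`, `flagged`.
#' @export
correlation_circle <- function(pca, radius = 0.8) {
  if (pca$n < 2L || pca$eigenvalues[2] <= 1e-12)
    stop("the first factorial plane requires rank >= 2", call. = FALSE)
  out <- data.frame(area = pca$col_labels,
                    phi1 = pca$phi[, 1], phi2 = pca$phi[, 2],
                    stringsAsFactors = FALSE)
  out$r <- sqrt(out$phi1^2 + out$phi2^2)
  out$flagged <- out$r >= radius
  out <- out[order(-out$r), ]
  rownames(out) <- NULL
  out
}

#' Kaiser retention count
#'
#' Number of correlation-scale eigenvalues strictly above 1, the
#' conventional number of principal components to retain.
#'
#' @param pca A `cost_pca`.
#' @param tol Numerical slack so that eigenvalues equal to 1 up to floating
#'   point (e.g. from an exactly diagonal correlation matrix) do not count.
#' @return Integer count.
#' @export
kaiser_count <- function(pca, tol = 1e-8) sum(pca$eigenvalues > 1 + tol)
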