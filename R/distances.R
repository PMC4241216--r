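#' Pairwise distances between management objects
#'
#' Computes the m x m distance structure between the rows of the
#' standardized matrix under one of three metrics:
#' \describe{
#'   \item{`euclidean`}{\eqn{d_{rs} = \sqrt{(x_r - x_s)(x_r - x_s)'}}; on a
#'     column-standardized matrix this is the standardized Euclidean
#'     distance.}
#'   \item{`mahalanobis`}{\eqn{d_{rs}^2 = (x_r - x_s)' V^{-} (x_r - x_s)}
#'     with `V` the sample covariance matrix (1/(m-1) denominator).  When
#'     `V` is singular -- unavoidable when there are at least as many areas
#'     as objects -- the Moore-Penrose pseudo-inverse is used and recorded.}
#'   \item{`cityblock`}{\eqn{d_{rs} = \sum_j |x_{rj} - x_{sj}|}.}
#' }
#'
#' @param X A `standardized_matrix` (or any numeric matrix with at least two
#'   rows).
#' @param metric One of `"euclidean"`, `"mahalanobis"`, `"cityblock"`.
#' @param rank_tol Relative rank tolerance used to decide whether the
#'   covariance matrix is singular.
#' @return A [stats::dist] object with attributes `metric` and, for
#'   Mahalanobis, `covariance`, `cov_inverse` and `inversion` (`"inverse"` or
#'   `"pseudoinverse"`).
#' @export
object_distances <- function(X, metric = c("euclidean", "mahalanobis",
                                           "cityblock"),
                             rank_tol = 1e-10) {
  metric <- match.arg(metric)
  X <- unclass(as.matrix(X))
  if (nrow(X) < 2L)
    stop("at least 2 objects are required to compute distances",
         call. = FALSE)
  D <- switch(metric,
    euclidean = stats::dist(X, method = "euclidean"),
    cityblock = stats::dist(X, method = "manhattan"),
    mahalanobis = {
      V <- stats::cov(X)
      ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
      singular <- min(ev) <= rank_tol * max(abs(ev))
      Vinv <- if (singular) MASS::ginv(V, tol = rank_tol) else solve(V)
      m <- nrow(X)
      d <- matrix(0, m, m)
      for (r in seq_len(m - 1L)) for (s in (r + 1L):m) {
        v <- X[r, ] - X[s, ]
        d[s, r] <- sqrt(max(0, drop(v %*% Vinv %*% v)))
      }
      out <- stats::as.dist(d)
      attr(out, "covariance") <- V
      attr(out, "cov_inverse") <- Vinv
      attr(out, "inversion") <- if (singular) "pseudoinverse" else "inverse"
      out
    })
  attr(D, "metric") <- metric
  attr(D, "Labels") <- rownames(X)
  D
}

## point-to-point distance in the same metric as a distance object,
## used for centroid and Ward linkage
point_distance <- function(u, v, metric, cov_inverse = NULL) {
  switch(metric,
    euclidean = sqrt(sum((u - v)^2)),
    cityblock = sum(abs(u - v)),
    mahalanobis = {
      w <- u - v
      sqrt(max(0, drop(w %*% cov_inverse %*% w)))
    })
}
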