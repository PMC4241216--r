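#' Plot the dendrogram of a merge tree
#'
#' @param x A `merge_tree`.
#' @param main Title; defaults to the linkage/metric pair.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.merge_tree <- function(x, main = NULL, ...) {
  if (is.null(main))
    main <- paste0("Hierarchical tree (", x$linkage, ", ", x$metric, ")")
  plot(as.hclust(x), main = main, xlab = "", sub = "", ...)
}

#' Plot a cluster-number validity profile
#'
#' Draws RSQ, SPRSQ, RMSSTD and the max-scaled pseudo-F against the number
#' of clusters on one 0-1 scale, marking the suggested k.
#'
#' @param x A `validity_profile`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.validity_profile <- function(x, ...) {
  y <- cbind(RSQ = x$rsq, SPRSQ = x$sprsq,
             RMSSTD = x$rmsstd / max(x$rmsstd),
             pF = x$pseudo_f_scaled)
  graphics::matplot(x$k, y, type = "b", pch = 1:4, lty = 1:4,
                    col = c("black", "blue", "darkgreen", "red"),
                    xlab = "number of clusters k", ylab = "index (scaled)",
                    main = "Determination of the optimal number of clusters",
                    ...)
  graphics::abline(v = attr(x, "suggested_k"), col = "grey", lty = 3)
  graphics::legend("right", legend = colnames(y), pch = 1:4, lty = 1:4,
                   col = c("black", "blue", "darkgreen", "red"), bty = "n")
  invisible(x)
}

#' Correlation circle of the first factorial plane
#'
#' Areas of variability plotted by their correlations with the first two
#' principal factors, inside the unit circle, with the interpretability
#' ring at `radius` highlighted.
#'
#' @param pca A `cost_pca`.
#' @param radius Interpretability ring radius.
#' @export
plot_correlation_circle <- function(pca, radius = 0.8) {
  cc <- correlation_circle(pca, radius)
  th <- seq(0, 2 * pi, length.out = 200)
  plot(cos(th), sin(th), type = "l", asp = 1, xlab = sprintf(
    "axis 1 (%.1f%%)", 100 * pca$proportions[1]),
    ylab = sprintf("axis 2 (%.1f%%)", 100 * pca$proportions[2]),
    main = "Areas of variability: correlation circle")
  graphics::lines(radius * cos(th), radius * sin(th), col = "red")
  graphics::abline(h = 0, v = 0, col = "grey", lty = 3)
  graphics::arrows(0, 0, cc$phi1, cc$phi2, length = 0.06,
                   col = ifelse(cc$flagged, "black", "grey"))
  graphics::text(cc$phi1, cc$phi2, cc$area, cex = 0.6, pos = 3,
                 col = ifelse(cc$flagged, "black", "grey40"))
  invisible(cc)
}

#' Object map on the first factorial plane
#'
#' @param pca A `cost_pca`.
#' @param labels Optional cluster labels used to colour the objects.
#' @export
plot_object_map <- function(pca, labels = NULL) {
  col <- if (is.null(labels)) "black" else labels + 1L
  plot(pca$psi[, 1], pca$psi[, 2], col = col, pch = 19, asp = 1,
       xlab = sprintf("axis 1 (%.1f%%)", 100 * pca$proportions[1]),
       ylab = sprintf("axis 2 (%.1f%%)", 100 * pca$proportions[2]),
       main = "Objects on the first factorial plane")
  graphics::abline(h = 0, v = 0, col = "grey", lty = 3)
  graphics::text(pca$psi[, 1], pca$psi[, 2], pca$row_labels, cex = 0.6,
                 pos = 3, col = col)
  invisible(pca$psi[, 1:2])
}

#' Plot the hierarchical tree over the principal-component map
#'
#' Simple three-dimensional rendering of an [embed_tree()] view: the
#' factorial plane is drawn in an oblique projection, leaves are placed at
#' their PC1-PC2 coordinates coloured by cluster, and tree segments rise to
#' the internal nodes at their merge heights.
#'
#' @param x An `hcpc_view`.
#' @param angle Oblique projection angle in radians.
#' @param height_scale Vertical exaggeration of merge heights.
#' @param ... Ignored.
#' @export
plot.hcpc_view <- function(x, angle = pi / 6, height_scale = NULL, ...) {
  nd <- x$nodes
  if (is.null(height_scale))
    height_scale <- diff(range(nd$x)) / max(nd$height)
  proj <- function(px, py, pz)
    list(x = px + cos(angle) * py * 0.5,
         y = pz * height_scale + sin(angle) * py * 0.5)
  p <- proj(nd$x, nd$y, nd$height)
  plot(range(p$x), range(p$y), type = "n", axes = FALSE,
       xlab = "", ylab = "",
       main = "Hierarchical tree over the PC1-PC2 map")
  ## ground-plane box
  bx <- range(nd$x); by <- range(nd$y)
  corners <- proj(bx[c(1, 2, 2, 1, 1)], by[c(1, 1, 2, 2, 1)], 0)
  graphics::lines(corners$x, corners$y, col = "grey70")
  for (i in seq_len(nrow(x$segments))) {
    a <- nd[x$segments$child[i], ]; b <- nd[x$segments$parent[i], ]
    pa <- proj(a$x, a$y, a$height); pb <- proj(b$x, b$y, b$height)
    graphics::segments(pa$x, pa$y, pb$x, pb$y, col = "grey30")
  }
  m <- length(x$labels)
  pl <- proj(nd$x[1:m], nd$y[1:m], 0)
  graphics::points(pl$x, pl$y, pch = 19, col = x$cut$labels + 1L)
  graphics::text(pl$x, pl$y, x$labels, cex = 0.55, pos = 1)
  invisible(x)
}
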