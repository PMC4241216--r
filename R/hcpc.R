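#' Embed a hierarchical tree over the principal-component map
#'
#' Combines cluster analysis and PCA into the three-dimensional display of
#' the hierarchy over the first factorial plane: every object (leaf) sits at
#' its coordinates on axes 1-2 with height 0, every internal node sits at
#' the centre of gravity of its member objects in the plane with height
#' equal to its merge height, and the tree is drawn as segments between
#' child and parent nodes.
#'
#' @param tree A `merge_tree`.
#' @param pca A `cost_pca` fitted on the same standardized matrix.
#' @param k Number of clusters for the flat partition colouring the leaves.
#' @return An `hcpc_view`: list with `nodes` (data frame of node id, x, y,
#'   height, size, kind), `segments` (data frame of child/parent node ids),
#'   `cut` (the [cut_tree()] result), `k`, and `labels`.
#' @export
embed_tree <- function(tree, pca, k) {
  if (tree$m != pca$m ||
      !identical(unname(tree$labels), unname(pca$row_labels)))
    stop("'tree' and 'pca' must be built from the same objects",
         call. = FALSE)
  m <- tree$m
  coords <- pca$psi[, 1:2, drop = FALSE]
  sets <- step_members(tree)
  nodes <- data.frame(
    node = seq_len(2L * m - 1L),
    x = c(coords[, 1], vapply(sets, function(s) mean(coords[s, 1]), 0)),
    y = c(coords[, 2], vapply(sets, function(s) mean(coords[s, 2]), 0)),
    height = c(rep(0, m), tree$height),
    size = c(rep(1L, m), tree$sizes),
    kind = rep(c("leaf", "internal"), c(m, m - 1L)))
  segments <- do.call(rbind, lapply(seq_len(m - 1L), function(t) {
    child <- ifelse(tree$merge[t, ] < 0, -tree$merge[t, ],
                    tree$merge[t, ] + m)
    data.frame(child = child, parent = m + t)
  }))
  structure(list(nodes = nodes, segments = segments,
                 cut = cut_tree(tree, k), k = k, labels = tree$labels),
            class = "hcpc_view")
}

#' @export
print.hcpc_view <- function(x, ...) {
  cat("Hierarchical tree embedded over the PC1-PC2 map: ",
      length(x$labels), " objects, k = ", x$k, " clusters\n", sep = "")
  for (i in seq_along(x$cut$members))
    cat("  cluster ", i, " (node ", x$cut$node_ids[i], "): ",
        paste(x$labels[x$cut$members[[i]]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Integrated interpretation report
#'
#' Gathers every stage of the variability analysis into one structured,
#' deterministic report: the metric/linkage scan and its winning pair, the
#' cluster-number validity profile and suggested k, the flat partition with
#' dendrogram node numbers, the PCA inertia decomposition, the per-axis top
#' contributors (objects and areas with contribution above the uniform
#' share), and the correlation-circle flags.
#'
#' @param scan A `combination_scan`.
#' @param profile A `validity_profile`.
#' @param pca A `cost_pca`.
#' @param view An `hcpc_view`.
#' @param n_axes Number of leading axes to describe (bounded by the rank).
#' @param ctr_threshold Contribution threshold as a multiple of the uniform
#'   share (1/m for objects, 1/n for areas).
#' @return A `variability_report` list.
#' @export
interpretation_report <- function(scan, profile, pca, view, n_axes = 2L,
                                  ctr_threshold = 1) {
  stages <- c(scan = !missing(scan) && inherits(scan, "combination_scan"),
              profile = !missing(profile) && inherits(profile,
                                                      "validity_profile"),
              pca = !missing(pca) && inherits(pca, "cost_pca"),
              view = !missing(view) && inherits(view, "hcpc_view"))
  if (!all(stages))
    stop("missing or invalid stage(s): ",
         paste(names(stages)[!stages], collapse = ", "),
         "; completed: ", paste(names(stages)[stages], collapse = ", "),
         call. = FALSE)
  n_axes <- min(n_axes, sum(pca$eigenvalues > 1e-12))
  axes <- lapply(seq_len(n_axes), function(a) {
    ci <- ctr_individuals(pca, a)
    cv <- ctr_variables(pca, a)
    list(axis = a,
         inertia_pct = 100 * pca$proportions[a],
         top_objects = names(sort(ci[ci > ctr_threshold / pca$m],
                                  decreasing = TRUE)),
         top_areas = names(sort(cv[cv > ctr_threshold / pca$n],
                                decreasing = TRUE)))
  })
  circle <- correlation_circle(pca)
  flagged <- circle[circle$flagged, ]
  ## flagged areas split by the side of axis 1 they load on
  axis1_groups <- list(
    positive = flagged$area[flagged$phi1 > 0],
    negative = flagged$area[flagged$phi1 < 0])
  clusters <- lapply(seq_along(view$cut$members), function(i) list(
    cluster = i, node = view$cut$node_ids[i],
    objects = view$labels[view$cut$members[[i]]]))
  structure(list(
    best_combination = scan$best,
    scan_table = scan$table,
    validity = as.data.frame(profile),
    suggested_k = suggest_k(profile),
    k_used = view$k,
    clusters = clusters,
    eigenvalues = pca$eigenvalues,
    inertia_cum_pct = 100 * pca$cum_proportions,
    kaiser = kaiser_count(pca),
    axes = axes,
    correlation_circle = circle,
    axis1_groups = axis1_groups),
    class = "variability_report")
}

#' @export
print.variability_report <- function(x, ...) {
  cat("== Health-cost variability report ==\n")
  cat("Clustering model: (", x$best_combination$linkage, ", ",
      x$best_combination$metric, "), cophenetic c = ",
      format(x$best_combination$c, digits = 6), "\n", sep = "")
  cat("Suggested number of clusters (pseudo-F): ", x$suggested_k,
      "; partition reported at k = ", x$k_used, "\n", sep = "")
  for (cl in x$clusters)
    cat("  cluster ", cl$cluster, " (node ", cl$node, "): ",
        paste(cl$objects, collapse = ", "), "\n", sep = "")
  cat("Inertia: axis 1-2 ", round(x$inertia_cum_pct[2], 2),
      "%, axis 1-3 ", round(x$inertia_cum_pct[3], 2),
      "%; eigenvalues > 1: ", x$kaiser, "\n", sep = "")
  for (ax in x$axes) {
    cat("Axis ", ax$axis, " (", round(ax$inertia_pct, 2), "%): objects ",
        paste(ax$top_objects, collapse = ", "), "\n", sep = "")
    cat("    areas: ", paste(ax$top_areas, collapse = ", "), "\n", sep = "")
  }
  cat("Well-represented areas on the plane (r >= 0.8), axis-1 side:\n")
  cat("  right: ", paste(x$axis1_groups$positive, collapse = ", "), "\n",
      sep = "")
  cat("  left:  ", paste(x$axis1_groups$negative, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Serialize a report to JSON or Markdown
#'
#' @param report A `variability_report`.
#' @param path Output file path.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  } else {
    txt <- utils::capture.output(print(report))
    writeLines(c("```", txt, "```"), path)
  }
  invisible(path)
}
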