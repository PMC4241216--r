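#' Read a labelled object-by-area matrix from CSV
#'
#' Expects one header row of area labels, one leading column of object
#' labels, and numeric cells with a `.` decimal point.  Ragged rows,
#' non-numeric cells (including comma decimals) and duplicate labels are
#' rejected with a located error.
#'
#' @param path CSV file path.
#' @return A `variability_matrix`.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  cells <- strsplit(lines, ",", fixed = TRUE)
  width <- lengths(cells)
  if (width[1] < 2L)
    stop("no data columns found; comma decimal separators with ",
         "semicolon delimiters are not supported -- use '.' decimals in a ",
         "comma-delimited file", call. = FALSE)
  if (length(unique(width)) != 1L)
    stop("ragged CSV: row ", which(width != width[1])[1], " has ",
         width[which(width != width[1])[1]], " fields, expected ", width[1],
         call. = FALSE)
  header <- cells[[1]][-1]
  body <- cells[-1]
  row_labels <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(row_labels) || anyDuplicated(header))
    stop("duplicate row or column labels", call. = FALSE)
  vals <- matrix(NA_real_, length(body), length(header))
  for (i in seq_along(body)) for (j in seq_along(header)) {
    cell <- trimws(body[[i]][j + 1L])
    v <- suppressWarnings(as.numeric(cell))
    if (is.na(v)) {
      hint <- if (grepl("^[0-9]+;[0-9]", cell) || grepl("^\"?[0-9]+,[0-9]",
                                                        cell))
        " (comma decimal separators are not supported; use '.')" else ""
      stop("non-numeric cell at row ", i, ", column ", j, ": '", cell, "'",
           hint, call. = FALSE)
    }
    vals[i, j] <- v
  }
  dimnames(vals) <- list(row_labels, header)
  variability_matrix(vals)
}

#' Write a labelled matrix to CSV
#'
#' Values are serialized with 12 significant digits, so that
#' `read_matrix_csv(write_matrix_csv(A, path))` round-trips losslessly at
#' that precision.
#'
#' @param m Matrix to write (any numeric matrix with dimnames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  m <- as.matrix(m)
  header <- paste(c("object", colnames(m)), collapse = ",")
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], formatC(m[i, ], format = "g", digits = 12)),
          collapse = ","), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Run the full variability-analysis pipeline
#'
#' Executes build/load -> standardize -> metric-linkage scan -> tree ->
#' validity profile -> PCA -> tree-over-map embedding -> report, and writes
#' every intermediate artifact to `out_dir` as plain text (CSV, JSON,
#' Newick).
#'
#' Exactly one input source must be given: a matrix CSV path, a ready-made
#' matrix object, patient-level `records` + `costs`, or `fixture = TRUE` for
#' the bundled example matrix.
#'
#' @param matrix_csv Path to an object-by-area matrix CSV.
#' @param matrix A `variability_matrix`.
#' @param records,costs Patient-level records and unit-cost table (see
#'   [build_matrix()]).
#' @param fixture Use the bundled example matrix.
#' @param metric,linkage Clustering model override; if `NULL` the
#'   cophenetic scan selects the pair.
#' @param k Number of clusters, or `"auto"` for the pseudo-F suggestion.
#' @param out_dir Output directory (created if missing).
#' @param cost_mode,discount_rate Passed to [build_matrix()].
#' @param figures Also render dendrogram/validity/PCA/embedding figures as
#'   SVG.
#' @param verbose Log each stage to stderr.
#' @return The `variability_report`, invisibly.
#' @export
run_pipeline <- function(matrix_csv = NULL, matrix = NULL, records = NULL,
                         costs = NULL, fixture = FALSE,
                         metric = NULL, linkage = NULL, k = "auto",
                         out_dir = ".", cost_mode = "weighted",
                         discount_rate = 0, figures = FALSE,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message("[costvar] ", ...)
  sources <- c(!is.null(matrix_csv), !is.null(matrix), !is.null(records),
               isTRUE(fixture))
  if (sum(sources) != 1L)
    stop("select exactly one input source: matrix_csv, matrix, ",
         "records+costs, or fixture = TRUE", call. = FALSE)
  A <- if (!is.null(matrix_csv)) read_matrix_csv(matrix_csv)
       else if (!is.null(matrix)) matrix
       else if (isTRUE(fixture)) table3_fixture()
       else {
         if (is.null(costs)) stop("'records' require a 'costs' table",
                                  call. = FALSE)
         build_matrix(records, costs, cost_mode = cost_mode,
                      discount_rate = discount_rate)
       }
  say("matrix A: ", nrow(A), " objects x ", ncol(A), " areas")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  X <- standardize(A)

  if (is.null(metric) != is.null(linkage))
    stop("override 'metric' and 'linkage' together, or neither",
         call. = FALSE)
  scan <- scan_combinations(X)
  if (!is.null(metric)) {
    scan$best <- list(metric = metric, linkage = linkage,
                      c = scan$table$c[scan$table$metric == metric &
                                         scan$table$linkage == linkage])
    scan$tree <- agglomerate(object_distances(X, metric), linkage, X = X,
                             warn_nonmetric = FALSE)
  }
  tree <- scan$tree
  say("clustering model: (", scan$best$linkage, ", ", scan$best$metric,
      "), c = ", format(scan$best$c, digits = 6))

  profile <- validity_profile(tree, X)
  k_used <- if (identical(k, "auto")) suggest_k(profile) else as.integer(k)
  if (!identical(k, "auto") && (k_used < 1L || k_used > nrow(A)))
    stop("'k' out of range", call. = FALSE)
  say("suggested k = ", suggest_k(profile), ", using k = ", k_used)

  pca <- fit_pca(X)
  view <- embed_tree(tree, pca, k_used)
  report <- interpretation_report(scan, profile, pca, view)

  out <- function(f) file.path(out_dir, f)
  write_matrix_csv(A, out("matrix_a.csv"))
  write_matrix_csv(X, out("matrix_x.csv"))
  utils::write.csv(scan$table, out("cophenetic_scan.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(profile), out("validity_profile.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(linkage = tree$linkage, metric = tree$metric, labels = tree$labels,
         merges = data.frame(step = seq_len(tree$m - 1L),
                             left = tree$merge[, 1], right = tree$merge[, 2],
                             height = tree$height, size = tree$sizes)),
    out("tree.json"), auto_unbox = TRUE, digits = NA)
  ape::write.tree(ape::as.phylo(as.hclust(tree)), out("tree.nwk"))
  eig <- data.frame(axis = seq_len(pca$n), eigenvalue = pca$eigenvalues,
                    proportion = pca$proportions,
                    cumulative = pca$cum_proportions)
  utils::write.csv(eig, out("pca_eigenvalues.csv"), row.names = FALSE)
  ind <- data.frame(object = pca$row_labels, psi1 = pca$psi[, 1],
                    psi2 = pca$psi[, 2], ctr1 = ctr_individuals(pca, 1),
                    ctr2 = ctr_individuals(pca, 2))
  utils::write.csv(ind, out("pca_individuals.csv"), row.names = FALSE)
  vars <- correlation_circle(pca)
  vars$ctr1 <- ctr_variables(pca, 1)[vars$area]
  vars$ctr2 <- ctr_variables(pca, 2)[vars$area]
  vars$cos2_1 <- cos2_variables(pca, 1)[vars$area]
  vars$cos2_2 <- cos2_variables(pca, 2)[vars$area]
  utils::write.csv(vars, out("pca_variables.csv"), row.names = FALSE)
  write_report(report, out("report.json"), "json")
  write_report(report, out("report.md"), "markdown")

  if (figures) {
    render <- function(f, code, width = 8, height = 6) {
      grDevices::svg(out(f), width = width, height = height)
      on.exit(grDevices::dev.off())
      code
    }
    render("dendrogram.svg", plot(tree))
    render("validity.svg", plot(profile))
    render("correlation_circle.svg", plot_correlation_circle(pca))
    render("object_map.svg", plot_object_map(pca, view$cut$labels))
    render("hcpc_tree.svg", plot(view))
  }
  say("artifacts written to ", normalizePath(out_dir))
  invisible(report)
}

#' Read or write a generator configuration as YAML
#'
#' Serializes a [generator_config()] (cohort sizes, relapse probabilities,
#' per-factor means/families, unit costs, year offsets, seed) so that
#' simulation scenarios can be versioned as plain text.
#'
#' @param path YAML file path.
#' @param config A `generator_config`.
#' @return `read_generator_config()` returns a `generator_config`;
#'   `write_generator_config()` returns `path` invisibly.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  generator_config(
    patients = unlist(raw$patients),
    relapse_prob = unlist(raw$relapse_prob),
    means = as.data.frame(raw$means, stringsAsFactors = FALSE),
    costs = as.data.frame(raw$costs, stringsAsFactors = FALSE),
    year_offset = unlist(raw$year_offset),
    seed = raw$seed)
}

#' @rdname read_generator_config
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  yaml::write_yaml(list(
    patients = as.list(config$patients),
    relapse_prob = as.list(config$relapse_prob),
    means = as.list(config$means),
    costs = as.list(config$costs),
    year_offset = as.list(config$year_offset),
    seed = config$seed), path)
  invisible(path)
}
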