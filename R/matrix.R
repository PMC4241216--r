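#' Discount a cost amount to present value
#'
#' Applies constant-rate annual discounting, `amount / (1 + rate)^years`.
#' The default rate of 4% per year follows the French Health Authority
#' recommendation used for both countries in the sarcoma application.
#'
#' @param amount Cost amount (EUR).
#' @param years Non-negative integer number of years from the reference date.
#' @param rate Annual discount rate, a fraction in `[0, 1)`.
#' @return The discounted amount.
#' @examples
#' discount(100, 0)            # 100
#' discount(100, 1)            # 96.15385
#' discount(100, 2, rate = 0.04)
#' @export
discount <- function(amount, years, rate = 0.04) {
  if (any(years < 0)) stop("'years' must be non-negative", call. = FALSE)
  if (any(rate < 0 | rate >= 1)) stop("'rate' must be in [0, 1)",
                                      call. = FALSE)
  amount / (1 + rate)^years
}

check_records <- function(records, objects) {
  needed <- c("patient_id", "country", "phase", "factor", "quantity")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("records are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"year_offset" %in% names(records)) records$year_offset <- 0L
  bad_phase <- setdiff(unique(records$phase), unique(objects$phase))
  if (length(bad_phase))
    stop("unknown phase label(s) in records: ",
         paste(bad_phase, collapse = ", "), call. = FALSE)
  bad_country <- setdiff(unique(records$country), unique(objects$country))
  if (length(bad_country))
    stop("unknown country label(s) in records: ",
         paste(bad_country, collapse = ", "), call. = FALSE)
  if (any(records$quantity < 0))
    stop("resource quantities must be non-negative", call. = FALSE)
  records
}

object_records <- function(records, object) {
  records[records$country == object$country & records$phase == object$phase, ,
          drop = FALSE]
}

#' Aggregate a quantity area for one management object
#'
#' Implements the quantity aggregation rule: the member final factors are
#' summed per patient, then averaged over the object's patients (the patients
#' of the object's country with at least one record in the object's phase).
#' Objects with no patients aggregate to 0.
#'
#' @param records Patient-level records: a data frame with columns
#'   `patient_id`, `country`, `phase`, `factor`, `quantity` and optionally
#'   `year_offset`.
#' @param object One row of [management_objects()].
#' @param area One quantity-area descriptor from the area configuration.
#' @return The non-negative mean per-patient sum.
#' @export
aggregate_quantity_area <- function(records, object, area) {
  if (!identical(area$kind, "quantity"))
    stop("'area' must be a quantity area", call. = FALSE)
  sub <- object_records(records, object)
  if (nrow(sub) == 0L) return(0)
  n_patients <- length(unique(sub$patient_id))
  rel <- sub[sub$factor %in% area$factors, , drop = FALSE]
  ## mean over patients of the per-patient factor sums (patients without
  ## rows for the member factors contribute 0)
  sum(rel$quantity) / n_patients
}

#' Assign a unit-cost area value for one management object
#'
#' Cost areas take the country's unit cost of the member factors, but only
#' for objects that actually use the resource: if the paired quantity area is
#' 0 the cost area is 0.  Two averaging modes are supported for multi-factor
#' areas: `"simple"` takes the plain country mean of the member unit costs;
#' `"weighted"` weights each member cost by the object's total usage of that
#' factor (and therefore varies between objects with different factor mixes).
#' Under `"weighted"`, costs are discounted to each usage year with
#' [discount()] when `discount_rate > 0`.
#'
#' @param costs Unit-cost table: a data frame with columns `country`,
#'   `factor` and `unit_cost` (EUR).
#' @param object One row of [management_objects()].
#' @param area One unit-cost area descriptor.
#' @param paired_quantity The object's value in the paired quantity area.
#' @param records Patient-level records; required for `mode = "weighted"`.
#' @param mode `"weighted"` (default) or `"simple"`.
#' @param discount_rate Annual discount rate applied in weighted mode.
#' @return The non-negative cost-area value.
#' @export
assign_cost_area <- function(costs, object, area, paired_quantity,
                             records = NULL, mode = c("weighted", "simple"),
                             discount_rate = 0) {
  mode <- match.arg(mode)
  if (!identical(area$kind, "unit_cost"))
    stop("'area' must be a unit-cost area", call. = FALSE)
  if (paired_quantity <= 0) return(0)
  cc <- costs[costs$country == object$country &
                costs$factor %in% area$factors, , drop = FALSE]
  missing <- setdiff(area$factors, cc$factor)
  used_factors <- area$factors
  if (mode == "weighted" && !is.null(records)) {
    sub <- object_records(records, object)
    rel <- sub[sub$factor %in% area$factors & sub$quantity > 0, , drop = FALSE]
    if (nrow(rel) > 0L) {
      used_factors <- unique(rel$factor)
      missing <- setdiff(used_factors, cc$factor)
    }
  }
  if (length(missing))
    stop("missing unit cost for factor(s) '",
         paste(missing, collapse = "', '"), "' in ", object$country,
         call. = FALSE)
  if (mode == "simple" || is.null(records)) {
    return(mean(cc$unit_cost[match(intersect(area$factors, cc$factor),
                                   cc$factor)]))
  }
  sub <- object_records(records, object)
  rel <- sub[sub$factor %in% area$factors & sub$quantity > 0, , drop = FALSE]
  if (nrow(rel) == 0L)  # resource counted in paired area but factors unpriced by usage
    return(mean(cc$unit_cost))
  unit <- cc$unit_cost[match(rel$factor, cc$factor)]
  disc <- discount(unit, rel$year_offset, discount_rate)
  sum(disc * rel$quantity) / sum(rel$quantity)
}

#' Build the object-by-area variability matrix A
#'
#' Aggregates patient-level resource-use records and a per-country unit-cost
#' table into the m x n matrix `A` of management objects (rows) by areas of
#' variability (columns): quantity areas via [aggregate_quantity_area()] and
#' unit-cost areas via [assign_cost_area()].
#'
#' @inheritParams assign_cost_area
#' @param records Patient-level records (see [aggregate_quantity_area()]).
#' @param objects Data frame of management objects; see
#'   [management_objects()].
#' @param areas Area configuration; see [sarcoma_area_config()].
#' @param cost_mode Averaging mode for multi-factor cost areas.
#' @return A `variability_matrix`: a numeric matrix with object labels as row
#'   names and area labels as column names, carrying the `objects` and
#'   `areas` definitions as attributes.
#' @export
build_matrix <- function(records, costs, objects = management_objects(),
                         areas = sarcoma_area_config(),
                         cost_mode = c("weighted", "simple"),
                         discount_rate = 0) {
  cost_mode <- match.arg(cost_mode)
  if (anyDuplicated(paste(objects$phase, objects$country)))
    stop("duplicate (phase, country) object", call. = FALSE)
  records <- check_records(records, objects)
  m <- nrow(objects); n <- length(areas)
  A <- matrix(0, m, n, dimnames = list(objects$label, area_labels(areas)))
  for (i in seq_len(m)) {
    obj <- objects[i, ]
    for (a in areas)
      if (a$kind == "quantity")
        A[i, a$index] <- aggregate_quantity_area(records, obj, a)
    for (a in areas)
      if (a$kind == "unit_cost")
        A[i, a$index] <- assign_cost_area(costs, obj, a,
                                          paired_quantity = A[i, a$paired],
                                          records = records, mode = cost_mode,
                                          discount_rate = discount_rate)
  }
  variability_matrix(A, objects = objects, areas = areas)
}

#' Construct a variability matrix from raw values
#'
#' @param values Numeric m x n matrix of non-negative object-by-area values.
#' @param objects Optional object definitions (row metadata).
#' @param areas Optional area definitions (column metadata).
#' @return A `variability_matrix` object.
#' @export
variability_matrix <- function(values, objects = NULL, areas = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("matrix values must be numeric", call. = FALSE)
  if (any(values < 0)) stop("matrix values must be non-negative", call. = FALSE)
  if (is.null(rownames(values)))
    rownames(values) <- paste("object", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste("area", seq_len(ncol(values)))
  structure(values, objects = objects, areas = areas,
            class = c("variability_matrix", "matrix"))
}

#' Column-standardize a variability matrix
#'
#' Centres and scales every area (column) to mean 0 and *population* standard
#' deviation 1, i.e. with the 1/m denominator
#' \deqn{x_{ij} = (\alpha_{ij} - \bar\alpha_j)/\sigma_j, \quad
#'       \sigma_j = \sqrt{\tfrac1m \sum_i (\alpha_{ij} - \bar\alpha_j)^2}.}
#' Columns that do not vary cannot be standardized; they correspond to
#' factors with no between-location variability, which are excluded from the
#' analysis upstream, so a zero-variance column raises an error naming it
#' rather than being dropped silently.
#'
#' @param A A `variability_matrix` or plain numeric matrix.
#' @return A `standardized_matrix`: the standardized numeric matrix with
#'   attributes `col_means` and `col_sds`.
#' @export
standardize <- function(A) {
  A <- unclass(as.matrix(A))
  m <- nrow(A)
  mu <- colMeans(A)
  sdev <- sqrt(colMeans(sweep(A, 2, mu)^2))
  zero <- sdev <= 0
  if (any(zero))
    stop("zero-variance column(s): ",
         paste(colnames(A)[zero], collapse = ", "),
         "; non-varying areas must be excluded before standardization",
         call. = FALSE)
  X <- sweep(sweep(A, 2, mu), 2, sdev, "/")
  structure(X, col_means = mu, col_sds = sdev,
            class = c("standardized_matrix", "matrix"))
}

is_standardized <- function(X, tol = 1e-6) {
  X <- unclass(as.matrix(X))
  all(abs(colMeans(X)) < tol) &&
    all(abs(sqrt(colMeans(sweep(X, 2, colMeans(X))^2)) - 1) < tol)
}
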