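#' Default area-of-variability configuration for sarcoma management
#'
#' Builds the canonical configuration of 16 areas of variability: 8 resource
#' categories, each split into a *quantity* area (resources used) and a
#' *unit-cost* area.  Every area groups a set of final factors of variability
#' (a single price or quantity element, e.g. the unit cost of a chest
#' radiograph); the default configuration carries 60 final factors in total
#' (30 quantity + 30 cost).
#'
#' Aggregation rules attached to each area:
#' \describe{
#'   \item{`sum_then_mean`}{quantity areas: sum the member factors per
#'     patient, then average over the object's patients.}
#'   \item{`mean_cost_if_used`}{multi-factor cost areas: country mean of the
#'     member unit costs, applied only to objects whose paired quantity area
#'     is positive.}
#'   \item{`direct_if_used`}{single-factor cost areas: the country unit cost
#'     itself, applied under the same positivity condition.}
#' }
#'
#' @return A list of 16 area descriptors, each with elements `index`, `label`,
#'   `kind` (`"quantity"` or `"unit_cost"`), `category`, `factors` (character
#'   vector of member final factors), `aggregation`, and `paired` (index of
#'   the quantity area a cost area is conditioned on, `NA` for quantity
#'   areas).
#' @seealso [management_objects()], [build_matrix()], [final_factors()]
#' @export
sarcoma_area_config <- function() {
  cat_factors <- list(
    biopsies = c("surgical biopsy", "micro-biopsy", "needle aspiration cytology"),
    hospital_admissions = c("days inpatient", "days outpatient"),
    imaging = c("chest radiograph", "colonoscopy", "computed tomography",
                "ultrasound", "magnetic resonance imaging"),
    external_consultations = "external consultation",
    transfusions = c("platelet packs", "red blood cell packs"),
    radiotherapy_sessions = "radiotherapy session",
    radiotherapy_preparation = "radiotherapy preparation",
    chemotherapy_drugs = c("Caelyx", "Carboplatin", "Cisplatin", "Deticene",
                           "Doxorubicin", "Etoposide", "Gemcitabine",
                           "Holoxan", "Ifosfamide", "Imatinib", "Melphalan",
                           "Vinorelbine", "Oxaliplatin", "Paclitaxel",
                           "Vincristine")
  )
  short <- c(biopsies = "biopsies", hospital_admissions = "days hospitalization",
             imaging = "imaging", external_consultations = "external consultations",
             transfusions = "transfusions", radiotherapy_sessions = "rad. sessions",
             radiotherapy_preparation = "rad. preparation",
             chemotherapy_drugs = "chemotherapy drugs")
  areas <- vector("list", 16L)
  for (i in seq_along(cat_factors)) {
    cat <- names(cat_factors)[i]
    areas[[i]] <- list(
      index = i, label = paste0("Q. ", short[[cat]]), kind = "quantity",
      category = cat, factors = cat_factors[[i]],
      aggregation = "sum_then_mean", paired = NA_integer_
    )
    areas[[i + 8L]] <- list(
      index = i + 8L, label = paste0("C. ", short[[cat]]), kind = "unit_cost",
      category = cat, factors = cat_factors[[i]],
      aggregation = if (length(cat_factors[[i]]) > 1L) "mean_cost_if_used"
                    else "direct_if_used",
      paired = i
    )
  }
  areas
}

#' Table of final factors of variability in a configuration
#'
#' @param areas An area configuration, as returned by [sarcoma_area_config()].
#' @return A data frame with one row per final factor: `name`, `category`,
#'   `kind` and `area_index`.  Names are unique within `(category, kind)`.
#' @export
final_factors <- function(areas = sarcoma_area_config()) {
  out <- do.call(rbind, lapply(areas, function(a) {
    data.frame(name = a$factors, category = a$category, kind = a$kind,
               area_index = a$index, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Management objects: phase-by-country observation units
#'
#' An object is one (management phase, country) pair, e.g. "diagnosis in
#' France".  The default grid of 6 phases and 2 countries yields the 12
#' objects of the sarcoma application, indexed country-within-phase so that
#' odd indices are the first country and even indices the second.
#'
#' @param phases Character vector of management phases, in order.
#' @param countries Character vector of countries, in order.
#' @return A data frame with columns `index`, `phase`, `country` and `label`.
#' @export
management_objects <- function(phases = c("diagnosis", "surgery",
                                          "chemotherapy", "radiotherapy",
                                          "follow-up without relapse",
                                          "follow-up with relapse"),
                               countries = c("France", "Italy")) {
  grid <- expand.grid(country = countries, phase = phases,
                      stringsAsFactors = FALSE)[, 2:1]
  if (anyDuplicated(paste(grid$phase, grid$country)))
    stop("duplicate (phase, country) object", call. = FALSE)
  cap <- function(s) paste0(toupper(substring(s, 1, 1)), substring(s, 2))
  data.frame(index = seq_len(nrow(grid)), grid,
             label = paste(cap(grid$phase), grid$country),
             stringsAsFactors = FALSE)
}

area_labels <- function(areas) vapply(areas, `[[`, character(1), "label")
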