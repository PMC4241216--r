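## run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic patient-level cost-data generator
#'
#' Describes a two-country oncology cohort with the structure the
#' variability analysis assumes: per (country, phase, final factor) mean
#' resource intensities with a dispersion family, per (country, factor) unit
#' costs, cohort sizes, relapse probabilities and a mandatory seed.
#'
#' Defaults emulate the sarcoma study conditions: 58 patients in France and
#' 161 in Italy, relapse probabilities 16/58 and 37/161 (the cohort's
#' relapsed/non-relapsed follow-up split), per-phase mean resource
#' intensities taken from the bundled example matrix (area totals split
#' evenly over member factors) and country unit costs spread around the
#' example cost-area values.  Dispersion families: `poisson` for counts,
#' `lognormal` (sdlog 0.5, mean-calibrated) for lengths of hospital stay,
#' `bernoulli` for per-drug administration flags, `fixed` for deterministic
#' intensities.
#'
#' @param patients Named integer vector: cohort size per country.
#' @param relapse_prob Named probability of relapse per country.
#' @param means Data frame `country`, `phase`, `factor`, `mean`, `family`;
#'   `NULL` for the defaults above.
#' @param costs Data frame `country`, `factor`, `unit_cost`; `NULL` for
#'   defaults.
#' @param year_offset Named vector mapping phase to years since diagnosis
#'   (used for discounting).
#' @param seed Integer seed (mandatory).
#' @param areas Area configuration the factors refer to.
#' @return A `generator_config` list.
#' @export
generator_config <- function(patients = c(France = 58L, Italy = 161L),
                             relapse_prob = c(France = 16 / 58,
                                              Italy = 37 / 161),
                             means = NULL, costs = NULL,
                             year_offset = c("diagnosis" = 0L, "surgery" = 0L,
                                             "chemotherapy" = 0L,
                                             "radiotherapy" = 0L,
                                             "follow-up without relapse" = 1L,
                                             "follow-up with relapse" = 2L),
                             seed, areas = sarcoma_area_config()) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory",
                                           call. = FALSE)
  if (any(patients < 1L)) stop("cohort sizes must be positive",
                               call. = FALSE)
  if (any(relapse_prob < 0 | relapse_prob > 1))
    stop("'relapse_prob' must be in [0, 1]", call. = FALSE)
  if (is.null(means)) means <- default_means(areas)
  if (is.null(costs)) costs <- default_costs(areas)
  if (any(means$mean < 0) || any(costs$unit_cost < 0))
    stop("means and unit costs must be non-negative", call. = FALSE)
  bad <- setdiff(unique(means$family),
                 c("poisson", "lognormal", "fixed", "bernoulli"))
  if (length(bad))
    stop("invalid dispersion family tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(patients = patients, relapse_prob = relapse_prob,
                 means = means, costs = costs, year_offset = year_offset,
                 seed = as.integer(seed), areas = areas),
            class = "generator_config")
}

## default per-factor mean intensities derived from the bundled example
## matrix: each (phase, country) quantity-area total is split evenly over
## the area's member factors
default_means <- function(areas = sarcoma_area_config()) {
  A <- table3_fixture()
  objects <- attr(A, "objects")
  rows <- list()
  for (i in seq_len(nrow(objects))) {
    for (a in areas) {
      if (a$kind != "quantity") next
      total <- unclass(A)[i, a$index]
      nf <- length(a$factors)
      fam <- if (a$category == "chemotherapy_drugs") "bernoulli"
             else if (a$category == "hospital_admissions") "lognormal"
             else "poisson"
      mu <- if (fam == "bernoulli") pmin(1, total / nf) else total / nf
      rows[[length(rows) + 1L]] <-
        data.frame(country = objects$country[i], phase = objects$phase[i],
                   factor = a$factors, mean = mu, family = fam,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## default unit costs: country cost-area values from the bundled matrix,
## spread +-20% across multi-factor areas so that usage-weighted country
## means vary between objects as in real tariff tables
default_costs <- function(areas = sarcoma_area_config()) {
  base <- list(France = c(biopsies = 59.5, hospital_admissions = 918.3,
                          imaging = 76.34, external_consultations = 90,
                          transfusions = 199.6, radiotherapy_sessions = 137,
                          radiotherapy_preparation = 439,
                          chemotherapy_drugs = 2.22),
               Italy = c(biopsies = 41.63, hospital_admissions = 602,
                         imaging = 76.24, external_consultations = 47.45,
                         transfusions = 26.3, radiotherapy_sessions = 150,
                         radiotherapy_preparation = 871.8,
                         chemotherapy_drugs = 2.98))
  rows <- list()
  for (ctry in names(base)) {
    for (a in areas) {
      if (a$kind != "unit_cost") next
      nf <- length(a$factors)
      v <- base[[ctry]][[a$category]]
      spread <- if (nf > 1L) v * (0.8 + 0.4 * (seq_len(nf) - 1) / (nf - 1))
                else v
      rows[[length(rows) + 1L]] <-
        data.frame(country = ctry, factor = a$factors, unit_cost = spread,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic patient-level cost dataset
#'
#' Draws reproducible patient-level resource-use records under a
#' [generator_config()]: every patient participates in the four treatment
#' phases, and in exactly one of the two follow-up phases according to a
#' Bernoulli relapse draw.  Per-record quantities follow the configured
#' dispersion family; empirical per-(country, phase, factor) means converge
#' to the configured means as the cohort grows.
#'
#' @param config A `generator_config`.
#' @return A list with `records` (data frame `patient_id`, `country`,
#'   `phase`, `factor`, `quantity`, `year_offset`) and `costs` (the unit-cost
#'   table).
#' @export
generate_patients <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    out <- list()
    for (ctry in names(config$patients)) {
      n <- config$patients[[ctry]]
      ids <- sprintf("%s%04d", toupper(substr(ctry, 1, 2)), seq_len(n))
      relapse <- stats::rbinom(n, 1L, config$relapse_prob[[ctry]]) == 1L
      for (ph in names(config$year_offset)) {
        take <- if (ph == "follow-up with relapse") relapse
                else if (ph == "follow-up without relapse") !relapse
                else rep(TRUE, n)
        if (!any(take)) next
        pid <- ids[take]
        mm <- config$means[config$means$country == ctry &
                             config$means$phase == ph, , drop = FALSE]
        for (j in seq_len(nrow(mm))) {
          mu <- mm$mean[j]
          q <- switch(mm$family[j],
            poisson = stats::rpois(length(pid), mu),
            lognormal = if (mu > 0)
              stats::rlnorm(length(pid), log(mu) - 0.125, 0.5)
              else numeric(length(pid)),
            bernoulli = stats::rbinom(length(pid), 1L, mu),
            fixed = rep(mu, length(pid)),
            stop("invalid dispersion family tag: ", mm$family[j],
                 call. = FALSE))
          out[[length(out) + 1L]] <- data.frame(
            patient_id = pid, country = ctry, phase = ph,
            factor = mm$factor[j], quantity = as.numeric(q),
            year_offset = config$year_offset[[ph]],
            stringsAsFactors = FALSE)
        }
      }
    }
    list(records = do.call(rbind, out), costs = config$costs)
  })
}

#' Transcribed oncology object-by-area example matrix
#'
#' The 12 x 16 matrix of management objects (6 phases x 2 countries) by
#' areas of variability (8 resource categories x quantity/unit-cost) for the
#' published two-region sarcoma cost study, transcribed from the printed
#' table and bundled as a plain CSV.
#'
#' Because the source table is typeset without cell delimiters, digit
#' grouping was reconstructed under two structural constraints: a cost area
#' is 0 exactly when its paired quantity area is 0, and hospital-admission
#' unit costs are country-constant (France 918.3, Italy 602).  These force a
#' unique reading of every cell; in particular the France
#' external-consultation unit cost reads 90 (not 9) and the France biopsy
#' unit cost 59.5.
#'
#' @return A `variability_matrix` with object and area metadata attached.
#' @export
table3_fixture <- function() {
  path <- system.file("extdata", "table3_matrix_a.csv", package = "costvar",
                      mustWork = TRUE)
  A <- read_matrix_csv(path)
  attr(A, "objects") <- management_objects()
  attr(A, "areas") <- sarcoma_area_config()
  A
}

#' Random non-negative matrix for property tests
#'
#' @param m,n Dimensions (`m >= 2`, `n >= 1`).
#' @param seed Integer seed.
#' @param max Upper bound of the uniform cell distribution.
#' @return A `variability_matrix` with no constant column.
#' @export
generate_random_matrix <- function(m, n, seed, max = 10) {
  if (m < 2L || n < 1L) stop("need m >= 2 and n >= 1", call. = FALSE)
  with_seed(seed, {
    vals <- matrix(stats::runif(m * n, 0, max), m, n)
    ## a.s. unnecessary, but guarantee the no-constant-column contract
    for (j in seq_len(n))
      while (stats::var(vals[, j]) == 0)
        vals[, j] <- stats::runif(m, 0, max)
    variability_matrix(vals)
  })
}
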