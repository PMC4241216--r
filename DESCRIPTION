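Package: costvar
Title: Locating Variability in Health-Cost Evaluations Across Locations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Explorative assessment of the transferability of health-economic
    cost evaluations between locations.  Patient-level resource-use records
    and per-country unit-cost tables are aggregated into a nested object
    (management phase x country) by area-of-variability matrix, which is then
    column-standardized and examined with agglomerative hierarchical
    clustering (five linkage criteria, three distance metrics, cophenetic
    correlation model selection, RSQ/SPRSQ/RMSSTD/pseudo-F cluster-number
    indices), principal component analysis with contribution and
    representation-quality diagnostics, and a combined display of the
    hierarchical tree over the principal-component map.  Includes a
    synthetic patient-level cost-data generator for validation and a
    transcribed oncology object-by-area example matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pracma,
    optparse
Config/testthat/edition: 3
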