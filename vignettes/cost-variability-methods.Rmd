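---
title: "Locating variability in health-cost evaluations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating variability in health-cost evaluations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costvar)
```

## The problem

Cost evaluations in oncology are expensive to produce and rarely repeated,
so decision makers routinely ask whether results obtained in one location
can substitute for local data in another.  `costvar` implements an
explorative answer: instead of modelling costs, it *locates* where the
variability between locations sits.  Every elementary price or quantity
that can differ between locations (the unit cost of a chest radiograph, the
number of surgical biopsies, ...) is a **final factor of variability**.
Final factors are grouped into homogeneous **areas of variability** (e.g.
"quantity of imaging"), and areas are evaluated per **management object** —
one (care phase, country) pair such as "diagnosis in France".  In the
default sarcoma configuration this gives 60 final factors inside
8 categories x 2 kinds = 16 areas, over 6 phases x 2 countries = 12
objects.

The resulting non-negative matrix `A` (objects x areas) is the single input
to all downstream analysis.  High between-object variability concentrated
in particular areas means the cost evaluation transfers poorly through
those areas.

## From patient records to the matrix

Quantity areas are aggregated as the mean over an object's patients of the
per-patient sum of the member factors.  Unit-cost areas take the country's
cost of the member factors, *conditioned on use*: an object whose paired
quantity area is 0 gets cost 0.  Two averaging modes exist for multi-factor
cost areas:

* `simple` — the plain country mean of member unit costs, the literal
  aggregation rule;
* `weighted` (default) — the mean weighted by the object's usage of each
  member factor.  This is the mode consistent with observed tables in which
  a country's "unit cost of imaging" varies between objects: different
  phases use different imaging mixes.  With one member factor, or uniform
  usage, the two modes coincide.

Costs can be discounted at a constant annual rate (default 4%/year where
discounting is requested, the convention of the French Health Authority)
via `discount()`; in weighted mode the builder discounts each usage record
by its year offset from diagnosis, so matrix cells are already-discounted
means.  Quantities are never discounted.

Columns are then standardized to mean 0 and **population** (1/m) standard
deviation 1.  The population form matters twice: it is the displayed
definition of the standardization, and it makes the cross-product matrix
`(1/m) X'X` an exact correlation matrix (unit diagonal), which the Kaiser
retention rule presupposes.  Most library defaults use the 1/(m-1) form;
the two differ only by a constant factor per column, which cancels from
every distance ranking, cophenetic correlation and inertia proportion, but
not from the unit-diagonal property.  A zero-variance column aborts with an
error naming the area: factors that do not vary between locations carry no
transferability information and must be excluded upstream, not silently
dropped.

## Cluster analysis

Distances between the standardized object profiles are computed with three
metrics — standardized Euclidean, Mahalanobis
(`d^2 = (x_r - x_s)' V^- (x_r - x_s)`, `V` the sample covariance), and city
block.  With more areas than objects `V` is necessarily singular; we use
the Moore-Penrose pseudo-inverse with a relative rank tolerance of 1e-10
and record that choice in the result.  This keeps the full
metric-by-linkage scan well defined without pretending `V` is invertible.

Agglomeration supports single, complete, average, centroid and Ward
linkage.  Single/complete/average are computed by Lance-Williams updates
(equivalent to their set definitions — the test suite proves equivalence
against a brute-force set-formula implementation on every random instance
with up to 6 objects); centroid and Ward are recomputed from cluster
centroids at every step to match their displayed definitions, with Ward's
height the incremental sum of squares
`(n_r n_s / (n_r + n_s)) d^2(centroids)`.  Centroid and Ward presuppose
Euclidean geometry; requesting them under another metric warns but
computes, so that the full 15-combination scan remains possible.  When two
merges tie exactly, the pair whose (smallest leaf, largest leaf) key is
lexicographically smallest wins — an arbitrary but deterministic rule.

The clustering model is selected by the cophenetic correlation coefficient
`c` between original and tree-induced distances, maximized over the 15
(metric, linkage) pairs; degenerate combinations are recorded as missing.
On the bundled example matrix the scan selects (average linkage, Euclidean
distance).

### Number of clusters

Four sums-of-squares indices are computed per candidate `k`: RSQ of the
cut, SPRSQ of the merge producing `k` clusters, RMSSTD of the newly formed
cluster (pooled-variance denominator `n_vars x (size - 1)`, singletons 0),
and the pseudo-F ratio `(SSB/(k-1)) / (SSW/(m-k))`, all evaluated on the
standardized matrix — the space the clusters were formed in.  The suggested
`k` is the global argmax of pseudo-F over `k in [2, m-1]`, ties broken
toward fewer clusters; the other three indices are reported for joint
display (`plot()` of the profile draws all four, pseudo-F max-scaled into
[0, 1]).  Profiles can be flat, with several local pseudo-F peaks of
similar height; the profile table is always reported so that a user who
prefers an earlier local peak can see it.

## Principal component analysis

The correlation matrix `(1/m) X'X` is diagonalized.  Reported per axis
`alpha`: the eigenvalue and its inertia share; object coordinates
`psi = X u`; area coordinates `phi(j) = sqrt(lambda) u(j)`, which equal the
correlation between area `j` and the factor (an identity the tests verify
numerically); contributions `CTR(i)`, `CTR(j)` (shares summing to 1 per
axis); and representation qualities `cos^2(j)`, which sum to 1 per area
over all axes because standardized areas have unit norm on the correlation
scale.  The correlation-circle summary lists each area's distance
`r_j = sqrt(phi_1^2 + phi_2^2)` from the origin of the first factorial
plane and flags areas with `r_j >= 0.8` (the conventional inner ring) as
interpretable.  Components with eigenvalue above 1 are counted for Kaiser
retention, with a 1e-8 slack so an exactly diagonal correlation matrix
retains none.

Eigenvector signs are fixed by making the largest-magnitude loading of each
axis positive.  Axis orientations are therefore deterministic but may be
mirrored relative to other software; interpretation (oppositions along an
axis) is unaffected.  For tied eigenvalues any orthonormal basis of the
tied block is acceptable, so tests on such cases assert only invariant
quantities (proportions, reconstructions), never individual vectors.

## The tree over the component map

`embed_tree()` combines both views: leaves sit at their (PC1, PC2)
coordinates at height 0, every internal node at the centre of gravity of
its member objects with height equal to its merge height.  The embedded
tree is the *clustering-space* tree — built on the full standardized matrix
and projected afterwards — not a re-clustering of retained component
scores.  Re-clustering scores would make the display internally consistent
with the plane but would change the partition being displayed; the overlay
keeps the clustering and its display identical.  (Re-clustering is easy to
do explicitly by calling `agglomerate()` on `pca$psi[, 1:k]`.)

`interpretation_report()` assembles the scan, the validity profile, the
partition (with dendrogram-style node numbers: leaves `1..m`, internal
nodes `m+1..2m-1` in merge order), per-axis top contributors (contribution
above the uniform share, configurable), and the correlation-circle flags
into one deterministic structure, serializable as JSON or Markdown.

## The synthetic cohort generator

Real patient-level oncology cost records are rarely shareable, so
`generator_config()` / `generate_patients()` emulate the structure the
analysis assumes: two countries (default cohort sizes 58 and 161), six
management phases, Bernoulli relapse (default probabilities 16/58 and
37/161) routing each patient to exactly one follow-up phase, per-factor
mean intensities with dispersion families — `poisson` for counts,
`lognormal` (sdlog 0.5, mean-calibrated) for skewed lengths of stay,
`bernoulli` for per-drug administration flags, `fixed` for deterministic
quantities — and per-country unit costs.  Default intensities are taken
from the bundled example matrix (area totals split evenly over member
factors) and default unit costs spread ±20% around the example cost-area
values so that usage-weighted means vary between objects, as in real tariff
tables.

The generator reproduces, by construction, the features the analysis
relies on: nested factor/area/object structure, country-specific prices,
usage-conditioned cost areas, heavy-tailed intensities.  It does **not**
emulate within-country centre effects, correlated resource use across
phases of one patient, censoring, or time-varying tariffs — so passing
tests demonstrate correctness of the computations, not robustness to every
real-data pathology.

Test problem sizes are chosen to keep the oracle checks exhaustive and the
suite quick: brute-force agglomeration agreement on all random instances
with up to 6 objects, sums-of-squares oracles up to 8 objects, law-of-
large-numbers checks at 10 000 patients for a single factor, and
planted-structure recovery on 8-object scenarios with 150 patients per
country over 20 seeds.  The planted scenario gives one country 20-fold
higher chemotherapy-drug prices while keeping other prices essentially
shared, and separates follow-up intensity into light/heavy profiles, so
the true 4-group structure (treatment x country, follow-ups pooled) is
unambiguous; the adjusted Rand index between it and the 4-cluster cut is
1.0 on every tested seed.

## The bundled example matrix

`table3_fixture()` ships a 12 x 16 matrix transcribed from a published
Franco-Italian sarcoma costing table.  The printed source runs all cell
values together without delimiters, so the transcription reconstructs digit
grouping under two structural constraints stated by the source's own
aggregation rules: a cost area is zero exactly when its paired quantity
area is zero, and hospital-admission unit costs are country-constant
(918.3 vs 602 EUR/day).  These constraints force a unique reading of every
cell; two cells warrant mention because a naive left-to-right reading
differs: the France biopsy unit cost is 59.5 (not 59.59) and the France
external-consultation unit cost is 90 (not 9).  All quantities reported by
the package for this matrix — the cophenetic scan, validity profile,
inertia decomposition and partitions shown by `run_pipeline(fixture =
TRUE)` and recomputed by `scripts/acceptance.R` — are computed from this
transcription at run time.

```{r example}
A <- table3_fixture()
X <- standardize(A)
scan <- scan_combinations(X)
scan$best
profile <- validity_profile(scan$tree, X)
suggest_k(profile)
pca <- fit_pca(X)
round(100 * pca$cum_proportions[1:3], 2)
```

## Numerical choices, in one place

* Population (1/m) standard deviations and the `(1/m) X'X` correlation
  normalization, for the unit-diagonal/Kaiser consistency argued above.
* Sample (1/(m-1)) covariance inside the Mahalanobis metric — the
  conventional meaning of "sample covariance matrix"; pseudo-inverse at
  relative rank tolerance 1e-10 when singular.
* Merge tie-break: lexicographically smallest (min leaf, max leaf) pair.
* Flat cuts stop the agglomeration after `m - k` steps (equivalent to
  removing the `k - 1` highest merges for monotone linkages, and still
  well defined when centroid linkage inverts heights).
* Singleton RMSSTD is 0; pseudo-F with zero within-cluster dispersion is
  reported as `Inf` rather than an error.
* Degenerate inputs fail loudly and early: fewer than 2 objects, constant
  distance vectors, zero-variance areas, non-standardized PCA input,
  mismatched tree/PCA object sets.
* All CSV serialization uses 12 significant digits and `.` decimals;
  comma-decimal files are rejected with a pointed message.

## Limitations

* The analysis is explorative: it locates variability but does not test
  hypotheses about its causes; regression modelling on the located areas
  is the natural follow-up and is out of scope.
* With few objects (12 in the default configuration) validity indices are
  noisy and pseudo-F profiles can be nearly flat; the suggested `k` should
  be read together with the full profile and the dendrogram.
* Mahalanobis distances under a pseudo-inverse depend on the numerical
  rank decision; they are reported with the inversion mode attached.
* The generator's independence assumptions (across factors and patients)
  understate real-world correlation; planted-structure recovery results
  are upper bounds on what correlated data would give.
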