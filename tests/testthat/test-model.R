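test_that("quantity areas average the per-patient factor sums", {
  areas <- make_areas(list(biopsies = c("surgical biopsy", "micro-biopsy")))
  objects <- management_objects("diagnosis", "France")
  records <- data.frame(
    patient_id = c("p1", "p1", "p2"),
    country = "France", phase = "diagnosis",
    factor = c("surgical biopsy", "micro-biopsy", "surgical biopsy"),
    quantity = c(1, 0, 3), year_offset = 0L)
  expect_equal(aggregate_quantity_area(records, objects[1, ], areas[[1]]), 2)

  empty <- records[0, ]
  expect_equal(aggregate_quantity_area(empty, objects[1, ], areas[[1]]), 0)
  expect_error(aggregate_quantity_area(records, objects[1, ], areas[[2]]),
               "quantity area")
})

test_that("cost areas apply country means only where the resource is used", {
  areas <- make_areas(list(imaging = c("xray", "ct"), consult = "visit"))
  objects <- management_objects("diagnosis", "France")
  costs <- data.frame(country = "France", factor = c("xray", "ct", "visit"),
                      unit_cost = c(100, 200, 150))
  cost_area <- areas[[3]]; single_area <- areas[[4]]
  expect_equal(assign_cost_area(costs, objects[1, ], cost_area,
                                paired_quantity = 0), 0)
  expect_equal(assign_cost_area(costs, objects[1, ], single_area,
                                paired_quantity = 2, mode = "simple"), 150)
  expect_equal(assign_cost_area(costs, objects[1, ], cost_area,
                                paired_quantity = 2, mode = "simple"), 150)
  expect_error(assign_cost_area(costs[1, ], objects[1, ], cost_area,
                                paired_quantity = 2, mode = "simple"),
               "missing unit cost")
})

test_that("usage-weighted cost areas reflect the object's factor mix", {
  areas <- make_areas(list(imaging = c("xray", "ct")))
  objects <- management_objects("diagnosis", "France")
  costs <- data.frame(country = "France", factor = c("xray", "ct"),
                      unit_cost = c(100, 200))
  records <- data.frame(patient_id = c("p1", "p1"), country = "France",
                        phase = "diagnosis", factor = c("xray", "ct"),
                        quantity = c(3, 1), year_offset = 0L)
  expect_equal(assign_cost_area(costs, objects[1, ], areas[[2]],
                                paired_quantity = 4, records = records,
                                mode = "weighted"),
               (3 * 100 + 1 * 200) / 4)
})

test_that("build_matrix produces the full object-by-area grid", {
  cfg <- generator_config(patients = c(France = 15L, Italy = 20L), seed = 7)
  g <- generate_patients(cfg)
  A <- build_matrix(g$records, g$costs)
  expect_equal(dim(unclass(A)), c(12L, 16L))
  expect_true(all(unclass(A) >= 0))
  ## cost cell is zero exactly when its paired quantity cell is zero
  Av <- unclass(A)
  expect_identical(unname(Av[, 9:16] == 0), unname(Av[, 1:8] == 0))

  zero <- g$records; zero$quantity <- 0
  Az <- build_matrix(zero, g$costs)
  expect_true(all(unclass(Az) == 0))

  one <- management_objects("diagnosis", "France")
  expect_error(build_matrix(g$records, g$costs, objects = rbind(one, one)),
               "duplicate")
  bad <- g$records; bad$phase[1] <- "palliative"
  expect_error(build_matrix(bad, g$costs), "unknown phase")
})

test_that("generated matrix cells converge to the configured means", {
  areas <- make_areas(list(biopsies = "needle"))
  objects <- management_objects("diagnosis", "France")
  cfg <- generator_config(
    patients = c(France = 10000L), relapse_prob = c(France = 0),
    means = data.frame(country = "France", phase = "diagnosis",
                       factor = "needle", mean = 2, family = "poisson"),
    costs = data.frame(country = "France", factor = "needle",
                       unit_cost = 50),
    year_offset = c(diagnosis = 0L), seed = 11, areas = areas)
  g <- generate_patients(cfg)
  A <- build_matrix(g$records, g$costs, objects = objects, areas = areas)
  expect_lt(abs(unclass(A)[1, 1] - 2), 0.05)  # 3 sd / sqrt(n) bound
  expect_equal(unclass(A)[1, 2], 50)
})

test_that("standardization yields population-scaled columns and fails on constants", {
  expect_equal(as.vector(standardize(matrix(c(0, 2), 2, 1))), c(-1, 1))
  Ac <- matrix(c(1, 2, 5, 5), 2, dimnames = list(NULL, c("varies", "flat")))
  expect_error(standardize(Ac), "flat")

  A <- table3_fixture()
  X <- standardize(A)
  expect_equal(attr(X, "col_means"), colMeans(unclass(A)))
  expect_equal(attr(X, "col_sds"), apply(unclass(A), 2, popsd))
  expect_true(all(abs(colMeans(unclass(X))) < 1e-9))
  expect_true(all(abs(apply(unclass(X), 2, popsd) - 1) < 1e-9))
})

test_that("discounting is exact and monotone", {
  expect_equal(discount(100, 0, 0.04), 100)
  expect_equal(discount(100, 1, 0.04), 100 / 1.04)
  expect_equal(discount(100, 2, 0.04), 100 / 1.04^2)
  expect_error(discount(100, -1), "non-negative")
  expect_error(discount(100, 1, rate = 1), "rate")
  yrs <- 0:10
  expect_true(all(diff(discount(100, yrs, 0.04)) < 0))
  expect_true(all(discount(100, 5, c(0.02, 0.04, 0.08)) ==
                    sort(discount(100, 5, c(0.02, 0.04, 0.08)),
                         decreasing = TRUE)))
})

test_that("the default configuration carries 12 objects, 16 areas, 60 factors", {
  expect_equal(nrow(management_objects()), 12L)
  areas <- sarcoma_area_config()
  expect_length(areas, 16L)
  expect_equal(sum(vapply(areas, function(a) a$kind == "quantity", TRUE)), 8L)
  ff <- final_factors(areas)
  expect_equal(nrow(ff), 60L)
  expect_false(anyDuplicated(ff[c("name", "category", "kind")]) > 0)
})
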