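# Parameter container, file I/O, population derivation, genotype risks,
# and the synthetic life table.

default_file <- system.file("extdata", "parameters_default.yaml",
                            package = "strokepgx")

test_that("bundled default file loads with the published design settings", {
  p <- load_parameters(default_file)
  expect_s3_class(p, "cea_params")
  expect_equal(p$test_cost, 60)
  expect_equal(p$staff_cost, 16.91)
  expect_equal(p$lambda, 20000)
  expect_equal(p$discount_rate, 0.035)
  expect_equal(p$start_age, 67)
  expect_equal(p$cohort_size, 60424)
  expect_equal(p$lof_prevalence, 0.25)
  expect_equal(p$rr_clopidogrel_noLoF, 0.702)
  expect_identical(unclass(p), unclass(cea_params()))
})

test_that("validation rejects out-of-range and unknown fields by name", {
  expect_error(cea_params(lof_prevalence = 1.5), "lof_prevalence")
  expect_error(cea_params(test_cost = -1), "test_cost")
  expect_error(cea_params(not_a_field = 1), "not_a_field")
  expect_error(cea_params(start_age = 80, max_age = 75), "start_age")
  expect_error(cea_params(lambda = 0), "lambda")
  expect_error(cea_params(drug_cost = c(clopidogrel = 1, dipyridamole = 2)),
               "drug_cost")
  f <- tempfile(fileext = ".yaml")
  writeLines("lof_prevalence: 0.25", f)
  expect_error(load_parameters(f), "schema_version")
  writeLines(c(readLines(default_file), "mystery_knob: 3"), f)
  expect_error(load_parameters(f), "mystery_knob")
  expect_error(load_parameters(tempfile()), "not found")
})

test_that("a degenerate all-zero-probability model is a valid input", {
  p <- quiet_params()
  expect_s3_class(p, "cea_params")
  fit <- cea(p, flat_life_table(0))
  expect_equal(fit$strategies$no_testing$nonfatal_strokes, 0)
})

test_that("parameter sets round-trip through save/load bit-identically", {
  for (sc in c("base_case", "randomized")) {
    p <- generate_fixture(sc, seed = 11)$params
    f <- tempfile(fileext = ".yaml")
    save_parameters(p, f)
    expect_identical(load_parameters(f), p, label = sc)
  }
})

test_that("an assumptions-block field may not shadow a top-level field", {
  f <- tempfile(fileext = ".yaml")
  lines <- readLines(default_file)
  writeLines(c(lines, "  test_cost: 10"), f)  # duplicates under assumptions
  expect_error(load_parameters(f), "test_cost")
})

test_that("population derivation reproduces the UK first-stroke cohort", {
  uk <- estimate_population(1.07, 66436000, 0.85)
  expect_identical(uk$first_strokes, 71087L)
  expect_identical(uk$ischaemic_strokes, 60424L)
  expect_identical(estimate_population(0, 123456, 0.5),
                   list(first_strokes = 0L, ischaemic_strokes = 0L))
  expect_identical(estimate_population(1.0, 1e6, 0.5)$ischaemic_strokes, 500L)
  expect_error(estimate_population(-1, 10, 0.5), "non-negative")
  expect_error(estimate_population(1, 10, 1.5), "ischaemic_fraction")
})

test_that("population derivation is homogeneous of degree 1 in population", {
  # scale factors and inputs chosen so rounding is exact at every scale
  base <- estimate_population(1.25, 1e6, 0.8)
  for (k in c(2, 5, 10)) {
    scaled <- estimate_population(1.25, k * 1e6, 0.8)
    expect_identical(scaled$first_strokes, as.integer(k * base$first_strokes))
    expect_identical(scaled$ischaemic_strokes,
                     as.integer(k * base$ischaemic_strokes))
  }
})

test_that("genotype risk stratification satisfies the mixture identity", {
  # no stratification effect at RR 1
  r <- derive_genotype_risks(0.05, 1, 0.25)
  expect_equal(r$p_noLoF, 0.05)
  expect_equal(r$p_LoF, 0.05)
  # the base-case inputs give the 2.79% non-carrier risk
  r <- derive_genotype_risks(0.03974, 0.702, 0.25)
  expect_equal(round(r$p_noLoF, 4), 0.0279)
  expect_equal(round(r$p_LoF, 4), 0.0753)
  # worked example solvable by hand
  r <- derive_genotype_risks(0.05, 0.8, 0.2)
  expect_equal(r$p_noLoF, 0.04)
  expect_equal(r$p_LoF, 0.09)
  # property: mixture identity to 1e-12 across random feasible inputs
  set.seed(42)
  for (i in 1:200) {
    p_avg <- runif(1, 0.001, 0.2)
    f <- runif(1, 0.05, 0.95)
    rr <- runif(1, 0.3, 1.2)
    r <- tryCatch(derive_genotype_risks(p_avg, rr, f), error = function(e) NULL)
    if (is.null(r)) next
    expect_lt(abs((1 - f) * r$p_noLoF + f * r$p_LoF - p_avg), 1e-12)
  }
  # infeasible: derived carrier risk above 1
  expect_error(derive_genotype_risks(0.5, 0.1, 0.05), "infeasible")
  expect_error(derive_genotype_risks(0.05, -1, 0.25), "positive")
  expect_error(derive_genotype_risks(0.05, 0.8, 0), "f_lof")
})

test_that("synthetic Gompertz life table is monotone, closed and exact", {
  lt <- generate_life_table(a = 1e-4, b = 0.09, start_age = 67,
                            max_age = 100)
  expect_true(all(diff(lt$q[-nrow(lt)]) >= 0))
  expect_equal(lt$q[nrow(lt)], 1)
  expect_equal(lt$q[lt$age == 67], 1 - exp(-1e-4 * exp(0.09 * 67)))
  expect_error(generate_life_table(a = 0), "positive")
  expect_error(generate_life_table(b = -1), "positive")
})

test_that("life tables round-trip through delimited text and are validated", {
  lt <- generate_life_table()
  f <- tempfile(fileext = ".tsv")
  save_life_table(lt, f)
  expect_identical(load_life_table(f), lt)
  bad <- lt; bad$q[nrow(bad)] <- 0.5
  expect_error(save_life_table(bad, f), "close with q = 1")
  bad <- lt[-3, ]
  expect_error(save_life_table(bad, f), "consecutive")
})
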