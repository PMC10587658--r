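# Probabilistic sensitivity analysis: distribution specs, moment matching,
# reproducible sampling, and summaries on the cost-effectiveness plane.

zero_psa <- function(...)
  cea_params(psa = list(cost_cv = 0, prob_se_frac = 0, rr_cv = 0,
                        overrides = list()), ...)

test_that("distribution families follow parameter support", {
  spec <- psa_distributions(cea_params())
  expect_identical(spec$test_cost$family, "gamma")
  expect_identical(spec$lof_prevalence$family, "beta")
  expect_identical(spec$utility_no_further_stroke$family, "beta")
  expect_identical(spec$rr_clopidogrel_noLoF$family, "lognormal")
  expect_identical(spec$`drug_cost.mrd_aspirin`$family, "gamma")
  expect_identical(spec$`p_chf.clopidogrel`$family, "fixed")  # point mass at 0
  expect_false("lambda" %in% names(spec))
  expect_false("discount_rate" %in% names(spec))
})

test_that("beta moment matching recovers the target mean", {
  # hand oracle: mean 0.25, se 0.05 -> nu = 0.25*0.75/0.0025 - 1 = 74
  mm <- strokepgx:::beta_moments(0.25, 0.05)
  expect_equal(mm$shape1, 18.5)
  expect_equal(mm$shape2, 55.5)
  set.seed(1)
  draws <- rbeta(1e5, mm$shape1, mm$shape2)
  expect_lt(abs(mean(draws) - 0.25), 3 * 0.05 / sqrt(1e5))
  expect_error(strokepgx:::beta_moments(0.25, 0.5), "too large")
})

test_that("zero dispersion collapses every draw to the point estimates", {
  p <- zero_psa()
  d <- sample_parameters(p, seed = 5)
  expect_identical(unclass(d), unclass(p))
})

test_that("sampling is reproducible and leaves the caller's RNG alone", {
  p <- cea_params()
  spec <- psa_distributions(p)
  d1 <- sample_parameters(p, spec, seed = 31)
  set.seed(999); before <- runif(1)
  set.seed(999)
  d2 <- sample_parameters(p, spec, seed = 31)
  expect_identical(d1, d2)
  expect_identical(runif(1), before)
  d3 <- sample_parameters(p, spec, seed = 32)
  expect_false(identical(d1, d3))
})

test_that("PSA runs are deterministic given the master seed", {
  p <- cea_params()
  lt <- generate_life_table()
  a <- run_psa(p, 2, seed = 17, life_table = lt)
  b <- run_psa(p, 2, seed = 17, life_table = lt)
  expect_identical(a$draws, b$draws)
})

test_that("a zero-dispersion PSA reproduces the deterministic base case", {
  p <- zero_psa()
  base <- cea(p)
  ps <- run_psa(p, 4, seed = 123)
  expect_true(all(ps$draws$delta_cost == base$delta_cost))
  expect_true(all(ps$draws$delta_qaly == base$delta_qaly))
  expect_true(all(ps$draws$nmb == base$nmb))
  expect_true(ps$p_cost_effective %in% c(0, 1))
})

test_that("cost-effectiveness classification via NHB and NMB agree exactly", {
  ps <- run_psa(cea_params(), 40, seed = 2)
  expect_identical(mean(ps$draws$nhb > 0), mean(ps$draws$nmb > 0))
  expect_identical(ps$p_cost_effective, mean(ps$draws$nhb > 0))
  expect_identical(ps$p_cost_saving, mean(ps$draws$delta_cost < 0))
})

test_that("shrinking dispersions pull the PSA mean to the base case", {
  base <- cea()
  tight <- cea_params(psa = list(cost_cv = 0.01, prob_se_frac = 0.01,
                                 rr_cv = 0.01, overrides = list()))
  ps <- run_psa(tight, 50, seed = 8)
  expect_lt(abs(mean(ps$draws$delta_qaly) - base$delta_qaly),
            0.1 * abs(base$delta_qaly))
  wide <- run_psa(cea_params(), 50, seed = 8)
  expect_gt(sd(wide$draws$delta_qaly), sd(ps$draws$delta_qaly))
})

test_that("the acceptability curve has its limiting behaviour", {
  ps <- run_psa(cea_params(), 40, seed = 21)
  cc <- ceac(ps, c(1e-9, 20000, 1e9))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  # lambda -> 0: probability cost-effective -> probability cost-saving
  expect_equal(cc$probability[1], ps$p_cost_saving)
  expect_error(ceac(ps, c(-1, 100)), "positive")
  expect_error(ceac(ps, numeric(0)), "positive")
  # iterations all in the dominant quadrant give a flat curve at 1
  dom <- structure(list(draws = data.frame(delta_cost = c(-10, -20),
                                           delta_qaly = c(0.1, 0.2))),
                   class = "cea_psa")
  expect_equal(ceac(dom, c(1, 1000))$probability, c(1, 1))
})

test_that("simulate() on a fitted model runs the PSA around its estimates", {
  fit <- cea()
  ps <- simulate(fit, nsim = 5, seed = 77)
  expect_s3_class(ps, "cea_psa")
  expect_equal(nrow(ps$draws), 5)
  ps2 <- run_psa(fit$params, 5, seed = 77, life_table = fit$life_table)
  expect_identical(ps$draws, ps2$draws)
  expect_output(print(ps), "iterations")
})
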