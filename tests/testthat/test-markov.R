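# Markov engine: transition matrices, cohort traces, outcome accumulation.

test_that("discount factors follow the closed form", {
  expect_equal(discount_factor(0.035, 0), 1)
  expect_equal(discount_factor(0.035, 1), 1 / 1.035)
  expect_equal(discount_factor(0, 0:10), rep(1, 11))
  expect_error(discount_factor(0.035, -1), "non-negative")
  expect_error(discount_factor(-0.01, 1), "non-negative")
})

test_that("transition matrix composes competing risks as specified", {
  # no events, no mortality: identity
  expect_equal(transition_matrix(0, 0, 0.2, 0), diag(5),
               ignore_attr = TRUE)
  # hand arithmetic from the stated composition
  M <- transition_matrix(0.0279, 0.0279, 0.2, 0.02)
  expect_equal(unname(M["no_stroke", ]),
               c(0.952658, 0.022320, 0, 0.005580, 0.019442))
  # rows sum to 1 and stay in [0,1] across random inputs; deaths absorb
  set.seed(3)
  for (i in 1:200) {
    M <- transition_matrix(runif(1), runif(1), runif(1), runif(1))
    expect_lt(max(abs(rowSums(M) - 1)), 1e-12)
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(unname(M["vascular_death", ]), c(0, 0, 0, 1, 0))
    expect_equal(unname(M["nonvascular_death", ]), c(0, 0, 0, 0, 1))
    # no transitions back to fewer-stroke states
    expect_equal(unname(M["two_plus", c("no_stroke", "one_stroke")]), c(0, 0))
  }
  expect_error(transition_matrix(1.2, 0, 0, 0), "infeasible")
})

test_that("the age-specific builder matches the low-level constructor", {
  p <- cea_params()
  lt <- generate_life_table()
  M <- build_transition_matrix("mrd_aspirin", p, 80, lt)
  expect_equal(M, transition_matrix(p$p_stroke_mrd_aspirin,
                                    p$p_stroke_mrd_aspirin,
                                    p$fatal_stroke_fraction,
                                    lt$q[lt$age == 80]))
  expect_error(build_transition_matrix("mrd_aspirin", p, 300, lt),
               "life-table range")
})

test_that("a riskless deathless cohort never leaves the entry state", {
  p <- quiet_params()
  lt <- flat_life_table(0)
  tr <- run_cohort(allocate_treatments("no_testing", p), p, lt)
  T_ <- nrow(tr$occupancy) - 1L
  # everyone stays put until the life table's forced closure at the top age
  expect_equal(tr$occupancy[seq_len(T_), "no_stroke"], rep(1, T_),
               ignore_attr = TRUE)
  expect_equal(sum(tr$flows[, c("new_nonfatal", "fatal_stroke")]), 0)
})

test_that("the engine reproduces an independent matrix-product oracle", {
  # a short-horizon single-regimen instance checked against explicit
  # matrix products built in the test
  p <- quiet_params(p_stroke_clopidogrel_avg = 0.08,
                    fatal_stroke_fraction = 0.25,
                    start_age = 67, max_age = 70)
  lt <- data.frame(age = 67:70, q = c(0.05, 0.05, 0.05, 1))
  tr <- run_cohort(allocate_treatments("no_testing", p), p, lt)
  start <- c(1, 0, 0, 0, 0)
  expected <- start
  for (age in 68:70) {
    M <- oracle_matrix(0.08, 0.08, 0.25, lt$q[lt$age == age])
    expected <- expected %*% M
    expect_lt(max(abs(tr$occupancy[age - 66, ] - expected)), 1e-10)
  }
})

test_that("occupancy is conserved, deaths absorb, and survival is monotone", {
  for (i in 1:25) {
    fx <- generate_fixture("randomized", seed = 100 + i)
    for (s in c("testing", "no_testing")) {
      tr <- run_cohort(allocate_treatments(s, fx$params), fx$params,
                       fx$life_table)
      expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-10)
      alive <- rowSums(tr$occupancy[, 1:3])
      expect_true(all(diff(alive) <= 1e-12))
      dead <- rowSums(tr$occupancy[, 4:5])
      expect_true(all(diff(dead) >= -1e-12))
      # life-table closure: the only survivors of the final cycle are that
      # cycle's non-fatal stroke events (mortality applies to the
      # stroke-free), so the residual is bounded by the stroke risk
      n <- length(alive)
      p_max <- max(fx$params$p_stroke_clopidogrel_avg,
                   fx$params$p_stroke_mrd_aspirin,
                   fx$params$p_stroke_aspirin,
                   derive_genotype_risks(fx$params$p_stroke_clopidogrel_avg,
                                         fx$params$rr_clopidogrel_noLoF,
                                         fx$params$lof_prevalence)$p_LoF)
      expect_lte(alive[n], alive[n - 1] * p_max *
                   (1 - fx$params$fatal_stroke_fraction) + 1e-12)
    }
  }
})

test_that("the aggregate trace is the allocation-weighted sum of sub-traces", {
  fx <- generate_fixture("randomized", seed = 55)
  tr <- run_cohort(allocate_treatments("testing", fx$params), fx$params,
                   fx$life_table)
  agg <- Reduce(`+`, lapply(tr$sub, function(s) s$weight * s$occupancy))
  expect_equal(tr$occupancy, agg)
  expect_equal(sum(vapply(tr$sub, function(s) s$weight, numeric(1))), 1,
               tolerance = 1e-12)
})

test_that("a single undiscounted person-year accrues its cost and utility", {
  # one cycle, no strokes, no deaths before the forced horizon closure,
  # no drug or adverse-event burden: the only accrual is one year in the
  # no-additional-stroke state
  p <- quiet_params(start_age = 67, max_age = 68,
                    annual_cost_nondisabling = 2087,
                    utility_no_further_stroke = 0.61)
  lt <- data.frame(age = 67:68, q = c(0, 1))
  alloc <- allocate_treatments("no_testing", p)
  tr <- run_cohort(alloc, p, lt)
  out <- accumulate_outcomes(tr, alloc, p)
  expect_equal(out$cost, 2087)
  expect_equal(out$qalys, 0.61)
  expect_equal(out$life_years, 1)
})

test_that("stroke states carry the decremented utility through accrual", {
  # force everyone into the one-additional-stroke state in cycle 1 and
  # compare the second cycle's QALY accrual with the decremented utility
  p <- quiet_params(p_stroke_clopidogrel_avg = 1, fatal_stroke_fraction = 0,
                    p_stroke_after_first_recurrence =
                      c(clopidogrel = 0, mrd_aspirin = 0, aspirin = 0),
                    start_age = 67, max_age = 69)
  lt <- data.frame(age = 67:69, q = c(0, 0, 1))
  alloc <- allocate_treatments("no_testing", p)
  tr <- run_cohort(alloc, p, lt)
  expect_equal(unname(tr$occupancy[2, "one_stroke"]), 1)
  out <- accumulate_outcomes(tr, alloc, p)
  # year 0 at utility 0.61 plus year 1 in the stroke state at 0.61 - 0.174
  expect_equal(out$qalys, 0.61 + 0.436)
})

test_that("discounting strictly shrinks any stream beyond the first cycle", {
  p0 <- cea_params(discount_rate = 0)
  p1 <- cea_params(discount_rate = 0.035)
  lt <- generate_life_table()
  for (s in c("testing", "no_testing")) {
    a <- allocate_treatments(s, p0)
    tr <- run_cohort(a, p0, lt)
    out0 <- accumulate_outcomes(tr, a, p0)
    out1 <- accumulate_outcomes(tr, a, p1)
    expect_gt(out0$cost, out1$cost)
    expect_gt(out0$qalys, out1$qalys)
  }
})

test_that("life-years and QALYs respect their bounds", {
  for (i in 1:10) {
    fx <- generate_fixture("randomized", seed = 200 + i)
    fit <- cea(fx$params, fx$life_table)
    horizon <- fx$params$max_age - fx$params$start_age
    for (s in c("testing", "no_testing")) {
      st <- fit$strategies[[s]]
      expect_lte(st$life_years, horizon)
      expect_lte(st$qalys, st$life_years *
                   fx$params$utility_no_further_stroke)
      expect_gte(st$qalys, 0)
    }
  }
})

test_that("half-cycle correction reduces accruals under mortality", {
  p <- cea_params()
  lt <- generate_life_table()
  a <- allocate_treatments("no_testing", p)
  tr <- run_cohort(a, p, lt)
  full <- accumulate_outcomes(tr, a, p)
  half <- accumulate_outcomes(tr, a, p, half_cycle = TRUE)
  expect_lt(half$cost, full$cost)
  expect_lt(half$qalys, full$qalys)
})

test_that("traces export as delimited text with one row per cycle", {
  p <- cea_params()
  tr <- run_cohort(allocate_treatments("testing", p), p,
                   generate_life_table())
  f <- tempfile(fileext = ".tsv")
  save_trace(tr, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), nrow(tr$occupancy))
  expect_true(all(c("cycle", "no_stroke", "fatal_stroke") %in% names(tab)))
})
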