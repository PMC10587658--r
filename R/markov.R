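# Five-state annual-cycle Markov cohort model of secondary stroke:
# no additional stroke, one additional stroke, two or more additional
# strokes, vascular death, non-vascular death.  Competing risks within a
# cycle are composed in a fixed order: the recurrent-stroke event (fatal
# with probability `fatal_stroke_fraction`) resolves first, then background
# mortality applies to patients without a stroke event that cycle.

STATES <- c("no_stroke", "one_stroke", "two_plus",
            "vascular_death", "nonvascular_death")

#' Present-value discount factor
#'
#' @param rate annual discount rate (e.g. 0.035).
#' @param t cycle index (non-negative integer; cycle 0 is undiscounted).
#' @return `(1 + rate)^-t`.
#' @examples
#' discount_factor(0.035, 0:3)
#' @export
discount_factor <- function(rate, t) {
  if (rate < 0) stop("discount rate must be non-negative", call. = FALSE)
  if (any(t < 0)) stop("cycle index must be non-negative", call. = FALSE)
  (1 + rate)^(-t)
}

# Annual recurrent-stroke probability for a (regimen, genotype group) cell.
# Clopidogrel risk is genotype-specific via the mixture identity; the
# alternative regimens act independently of CYP2C19 genotype.
stroke_risk <- function(params, regimen, group) {
  if (regimen == "clopidogrel") {
    r <- derive_genotype_risks(params$p_stroke_clopidogrel_avg,
                               params$rr_clopidogrel_noLoF,
                               params$lof_prevalence)
    if (group == "LoF") r$p_LoF else r$p_noLoF
  } else if (regimen == "mrd_aspirin") {
    params$p_stroke_mrd_aspirin
  } else if (regimen == "aspirin") {
    params$p_stroke_aspirin
  } else stop("unknown regimen '", regimen, "'", call. = FALSE)
}

# Risk of a further stroke from the one-additional-stroke (and two-plus)
# state; defaults to the cell's first-recurrence risk.
further_stroke_risk <- function(params, regimen, group) {
  v <- params$p_stroke_after_first_recurrence
  if (is.null(v)) stroke_risk(params, regimen, group) else v[[regimen]]
}

#' Single-cycle transition matrix
#'
#' Builds the 5x5 row-stochastic transition matrix for one annual cycle from
#' the cycle's recurrent-stroke probabilities, the fatal fraction of
#' recurrent strokes, and the background (non-vascular) death probability.
#' From a living state with stroke probability `p`: a fatal recurrence
#' (probability `p * f`) moves to vascular death; a non-fatal recurrence
#' (`p * (1 - f)`) advances the stroke count (recurrences from the two-plus
#' state remain there); patients without a stroke event die of other causes
#' with probability `q`, else stay.  Death states are absorbing.
#'
#' @param p_first annual probability of recurrent stroke from the
#'   no-additional-stroke state.
#' @param p_further annual probability of a further stroke from the
#'   one-additional-stroke and two-plus states.
#' @param fatal_fraction fraction of recurrent strokes that are immediately
#'   fatal.
#' @param q annual background death probability.
#' @return A 5x5 matrix with `STATES` dimnames; every row sums to 1.
#' @export
transition_matrix <- function(p_first, p_further, fatal_fraction, q) {
  probs <- c(p_first, p_further, fatal_fraction, q)
  if (any(probs < 0) || any(probs > 1))
    stop_infeasible("infeasible parameters: transition inputs outside [0, 1]")
  M <- matrix(0, 5, 5, dimnames = list(STATES, STATES))
  fill <- function(from, p, next_state) {
    M[from, "vascular_death"] <<- p * fatal_fraction
    M[from, next_state] <<- M[from, next_state] + p * (1 - fatal_fraction)
    M[from, "nonvascular_death"] <<- (1 - p) * q
    M[from, from] <<- M[from, from] + (1 - p) * (1 - q)
  }
  fill("no_stroke", p_first, "one_stroke")
  fill("one_stroke", p_further, "two_plus")
  fill("two_plus", p_further, "two_plus")
  M["vascular_death", "vascular_death"] <- 1
  M["nonvascular_death", "nonvascular_death"] <- 1
  M
}

#' Age- and regimen-specific transition matrix
#'
#' Convenience wrapper resolving the cycle's inputs from a parameter set and
#' a life table: the recurrent-stroke probability for the (regimen, genotype
#' group) cell, the same or a configured further-recurrence risk, the fatal
#' fraction, and the background mortality at `age`.
#'
#' @param regimen `"clopidogrel"`, `"mrd_aspirin"` or `"aspirin"`.
#' @param params a `cea_params` object.
#' @param age integer age used for the life-table lookup.
#' @param life_table a life-table `data.frame` (see [generate_life_table()]).
#' @param group genotype group, `"noLoF"` or `"LoF"` (only affects
#'   clopidogrel).
#' @return A 5x5 transition matrix.
#' @export
build_transition_matrix <- function(regimen, params, age, life_table,
                                    group = "noLoF") {
  transition_matrix(stroke_risk(params, regimen, group),
                    further_stroke_risk(params, regimen, group),
                    params$fatal_stroke_fraction,
                    lookup_q(life_table, age))
}

# Trace one (group, regimen) sub-cohort from full occupancy of no_stroke.
# Cycle k (k = 1..T, T = max_age - start_age) spans ages
# [start_age + k - 1, start_age + k); background mortality is evaluated at
# the age attained at the end of the cycle, so the table's q = 1 at max_age
# closes the cohort by the horizon.
run_subcohort <- function(params, regimen, group, life_table) {
  T_ <- params$max_age - params$start_age
  p1 <- stroke_risk(params, regimen, group)
  p2 <- further_stroke_risk(params, regimen, group)
  f <- params$fatal_stroke_fraction
  occ <- matrix(0, T_ + 1L, 5L, dimnames = list(0:T_, STATES))
  occ[1L, "no_stroke"] <- 1
  flows <- matrix(0, T_, 3L,
                  dimnames = list(1:T_, c("new_nonfatal", "fatal_stroke",
                                          "nonstroke_death")))
  for (k in seq_len(T_)) {
    q <- lookup_q(life_table, params$start_age + k)
    M <- transition_matrix(p1, p2, f, q)
    v <- occ[k, ]
    occ[k + 1L, ] <- v %*% M
    living <- v[c("no_stroke", "one_stroke", "two_plus")]
    p_vec <- c(p1, p2, p2)
    flows[k, "new_nonfatal"] <- sum(living * p_vec) * (1 - f)
    flows[k, "fatal_stroke"] <- sum(living * p_vec) * f
    flows[k, "nonstroke_death"] <- sum(living * (1 - p_vec)) * q
  }
  list(occupancy = occ, flows = flows, regimen = regimen, group = group)
}

#' Run the cohort model for one strategy
#'
#' Traces every (genotype group, regimen) sub-cohort implied by a treatment
#' allocation through the five-state model, one annual cycle at a time from
#' the cohort entry age to the model's top age, and aggregates the traces
#' weighted by the allocation fractions.  Everyone enters in the
#' no-additional-stroke state.
#'
#' @param allocation a `cea_allocation` from [allocate_treatments()].
#' @param params a `cea_params` object.
#' @param life_table a life table covering ages `start_age` to `max_age`.
#' @return An object of class `cea_trace`: a list with `occupancy` (matrix of
#'   state proportions, one row per cycle 0..T), `flows` (per-cycle event
#'   flows: new non-fatal strokes, fatal strokes, non-stroke deaths), and
#'   `sub` (the per-cell traces and weights used for costing).
#' @export
run_cohort <- function(allocation, params, life_table) {
  stopifnot(inherits(allocation, "cea_allocation"))
  cells <- allocation[allocation$fraction > 0, , drop = FALSE]
  subs <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    s <- run_subcohort(params, cells$regimen[i], cells$group[i], life_table)
    s$weight <- cells$fraction[i]
    subs[[i]] <- s
  }
  occupancy <- Reduce(`+`, lapply(subs, function(s) s$weight * s$occupancy))
  flows <- Reduce(`+`, lapply(subs, function(s) s$weight * s$flows))
  structure(list(occupancy = occupancy, flows = flows, sub = subs,
                 strategy = attr(allocation, "strategy"),
                 start_age = params$start_age),
            class = "cea_trace")
}

#' @export
print.cea_trace <- function(x, ...) {
  T_ <- nrow(x$occupancy) - 1L
  cat("Cohort trace,", x$strategy, "strategy:", T_, "annual cycles from age",
      x$start_age, "\n")
  alive <- rowSums(x$occupancy[, c("no_stroke", "one_stroke", "two_plus")])
  show <- unique(round(seq(0, T_, length.out = 5)))
  print(round(cbind(x$occupancy[show + 1L, ], alive = alive[show + 1L]), 4))
  invisible(x)
}

#' Discounted costs and QALYs for a traced strategy
#'
#' Accumulates, cycle by cycle, the annual health-state treatment costs, the
#' regimen's drug and adverse-event treatment costs, one-off event costs
#' (non-fatal recurrent strokes split disabling/non-disabling by
#' `disabling_fraction`, fatal strokes, non-stroke deaths), state utilities,
#' and expected adverse-event disutilities.  Cycle 0 accrues undiscounted;
#' cycle t is discounted by `(1 + discount_rate)^-t`.  The strategy's
#' up-front testing cost is added once at entry, undiscounted.  The
#' no-additional-stroke and one-additional-stroke states carry the
#' non-disabling annual treatment cost; the two-plus state carries the
#' disabling annual cost.  Both post-recurrence states take the utility
#' `utility_no_further_stroke - utility_decrement_per_stroke_state`.
#'
#' @param trace a `cea_trace` from [run_cohort()].
#' @param allocation the `cea_allocation` the trace was run from.
#' @param params a `cea_params` object.
#' @param half_cycle if `TRUE`, continuous (state-occupancy) accruals use the
#'   mean of the cycle's start and end occupancy instead of the start
#'   (half-cycle correction); event flows are unaffected.  Default `FALSE`.
#' @return A list with `cost` and `qalys` (discounted, per patient), plus
#'   undiscounted `life_years` and cumulative event counts per patient.
#' @export
accumulate_outcomes <- function(trace, allocation, params,
                                half_cycle = FALSE) {
  stopifnot(inherits(trace, "cea_trace"))
  if (!identical(trace$strategy, attr(allocation, "strategy")))
    stop("trace and allocation come from different strategies", call. = FALSE)
  u0 <- params$utility_no_further_stroke
  us <- u0 - params$utility_decrement_per_stroke_state
  state_cost <- c(params$annual_cost_nondisabling,
                  params$annual_cost_nondisabling,
                  params$annual_cost_disabling, 0, 0)
  state_util <- c(u0, us, us, 0, 0)
  onecost_nonfatal <- params$disabling_fraction * params$onecost_disabling +
    (1 - params$disabling_fraction) * params$onecost_nondisabling
  total_cost <- attr(allocation, "upfront_cost")
  total_qaly <- 0
  life_years <- 0
  for (s in trace$sub) {
    T_ <- nrow(s$occupancy) - 1L
    start_occ <- s$occupancy[seq_len(T_), , drop = FALSE]
    occ <- if (half_cycle)
      (start_occ + s$occupancy[seq_len(T_) + 1L, , drop = FALSE]) / 2
    else start_occ
    alive <- rowSums(occ[, 1:3, drop = FALSE])
    ann_cost <- params$drug_cost[[s$regimen]] + params$ae_cost[[s$regimen]]
    ae_disutil <- params$p_minor_bleed[[s$regimen]] * params$disutility_minor_bleed +
      params$p_major_bleed[[s$regimen]] * params$disutility_major_bleed +
      params$p_chf[[s$regimen]] * params$disutility_chf
    cyc_cost <- drop(occ %*% state_cost) + alive * ann_cost +
      s$flows[, "new_nonfatal"] * onecost_nonfatal +
      s$flows[, "fatal_stroke"] * params$onecost_fatal_stroke +
      s$flows[, "nonstroke_death"] * params$onecost_nonstroke_death
    cyc_qaly <- drop(occ %*% state_util) - alive * ae_disutil
    disc <- discount_factor(params$discount_rate, seq_len(T_) - 1L)
    total_cost <- total_cost + s$weight * sum(cyc_cost * disc)
    total_qaly <- total_qaly + s$weight * sum(cyc_qaly * disc)
    life_years <- life_years +
      s$weight * sum(rowSums(start_occ[, 1:3, drop = FALSE]))
  }
  events <- colSums(trace$flows)
  list(cost = total_cost, qalys = total_qaly, life_years = life_years,
       nonfatal_strokes = unname(events["new_nonfatal"]),
       fatal_strokes = unname(events["fatal_stroke"]))
}

#' Write a cohort trace as delimited text
#'
#' One row per cycle: state occupancies plus the cycle's event flows.
#'
#' @param trace a `cea_trace`.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
save_trace <- function(trace, path) {
  T_ <- nrow(trace$occupancy) - 1L
  out <- data.frame(cycle = 0:T_, trace$occupancy,
                    rbind(NA_real_, trace$flows), check.names = FALSE)
  utils::write.table(format(out, digits = 17, scientific = FALSE), path,
                     quote = FALSE, row.names = FALSE, sep = "\t", na = "")
  invisible(path)
}
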