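# Incremental economics.  Strategy ordering is fixed throughout: subscript 2
# is the CYP2C19-testing pathway, subscript 1 is current prescribing, so
# delta = testing - no_testing.

#' Incremental cost-effectiveness ratio
#'
#' `ICER = (C2 - C1) / (QALY2 - QALY1)`.  Quadrants where the ratio is not a
#' meaningful number return a label: `"dominant"` (cheaper and at least as
#' effective), `"dominated"` (costlier and at most as effective),
#' `"equivalent"` (no difference in either dimension).
#'
#' @param delta_cost incremental cost (testing minus no testing).
#' @param delta_qaly incremental QALYs.
#' @return A number (GBP per QALY) or one of the three labels.
#' @examples
#' icer(-512, 0.107)   # "dominant"
#' icer(200, 0.01)     # 20000
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_cost == 0 && delta_qaly == 0) return("equivalent")
  if (delta_cost <= 0 && delta_qaly >= 0) return("dominant")
  if (delta_cost >= 0 && delta_qaly <= 0) return("dominated")
  delta_cost / delta_qaly
}

#' Net health benefit
#'
#' `NHB = dQALY - dCost / lambda`: the incremental health gain net of the
#' health forgone elsewhere in the system by spending `dCost` at an
#' opportunity cost of `lambda` per QALY.  Positive values indicate the
#' intervention is cost-effective at `lambda`.
#'
#' @param delta_qaly incremental QALYs per patient.
#' @param delta_cost incremental cost per patient.
#' @param lambda willingness-to-pay threshold (GBP per QALY, > 0).
#' @return Net health benefit in QALYs.
#' @examples
#' nhb(0.107, -512, 20000)
#' @export
nhb <- function(delta_qaly, delta_cost, lambda) {
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  delta_qaly - delta_cost / lambda
}

#' Net monetary benefit
#'
#' `NMB = dQALY * lambda - dCost`; identically `lambda` times the net health
#' benefit.
#'
#' @inheritParams nhb
#' @return Net monetary benefit in GBP.
#' @examples
#' nmb(0.107, -512, 20000)
#' @export
nmb <- function(delta_qaly, delta_cost, lambda) {
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  delta_qaly * lambda - delta_cost
}

#' Scale a per-patient quantity to the eligible population
#'
#' Multiplies an unrounded per-patient value by the cohort size.  Display
#' rounding is left to the caller; downstream arithmetic should use the
#' unrounded product.
#'
#' @param per_patient per-patient value (e.g. NHB or NMB).
#' @param n population size (non-negative).
#' @return `per_patient * n`.
#' @examples
#' scale_to_population(2652, 60424)
#' @export
scale_to_population <- function(per_patient, n) {
  if (n < 0) stop("population size must be non-negative", call. = FALSE)
  per_patient * n
}

#' Run the cost-effectiveness model
#'
#' The package's main entry point.  For each strategy (current prescribing
#' and CYP2C19 point-of-care testing) it resolves the prescribing decision
#' tree, traces the five-state Markov cohort model over the lifetime
#' horizon, and accumulates discounted costs and QALYs; it then performs the
#' incremental analysis (ICER or dominance, net health and monetary benefit
#' at the model's willingness-to-pay threshold, population-scaled totals,
#' and strokes prevented across the cohort).
#'
#' @param params a `cea_params` object (default [cea_params()]).
#' @param life_table a life table covering `[start_age, max_age]`; by
#'   default a synthetic Gompertz table from [generate_life_table()].
#' @param half_cycle apply a half-cycle correction to state-occupancy
#'   accruals (default `FALSE`).
#' @param test_failure_rate passed to [allocate_treatments()].
#' @return An object of class `cea`: per-strategy results under
#'   `$strategies` (allocation, trace, discounted `cost` and `qalys`,
#'   life-years, per-patient event counts), and incremental fields
#'   `delta_cost`, `delta_qaly`, `icer`, `nhb`, `nmb`, population totals
#'   `nhb_total`/`nmb_total`, and `strokes_prevented` (non-fatal and fatal
#'   counts across the cohort).
#' @examples
#' fit <- cea()
#' fit
#' summary(fit)
#' @export
cea <- function(params = cea_params(), life_table = NULL,
                half_cycle = FALSE, test_failure_rate = 0) {
  params <- validate_params(params)
  if (is.null(life_table))
    life_table <- generate_life_table(start_age = params$start_age,
                                      max_age = params$max_age)
  else
    life_table <- validate_life_table(life_table)
  if (min(life_table$age) > params$start_age ||
      max(life_table$age) < params$max_age)
    stop("life table does not cover ages ", params$start_age, " to ",
         params$max_age, call. = FALSE)
  strategies <- list()
  for (s in STRATEGIES) {
    alloc <- allocate_treatments(s, params, test_failure_rate)
    trace <- run_cohort(alloc, params, life_table)
    out <- accumulate_outcomes(trace, alloc, params, half_cycle)
    strategies[[s]] <- c(list(allocation = alloc, trace = trace), out)
  }
  dc <- strategies$testing$cost - strategies$no_testing$cost
  dq <- strategies$testing$qalys - strategies$no_testing$qalys
  n <- params$cohort_size
  res <- list(
    params = params, life_table = life_table, half_cycle = half_cycle,
    strategies = strategies,
    delta_cost = dc, delta_qaly = dq,
    icer = icer(dc, dq),
    nhb = nhb(dq, dc, params$lambda),
    nmb = nmb(dq, dc, params$lambda),
    nhb_total = scale_to_population(nhb(dq, dc, params$lambda), n),
    nmb_total = scale_to_population(nmb(dq, dc, params$lambda), n),
    strokes_prevented = list(
      nonfatal = (strategies$no_testing$nonfatal_strokes -
                    strategies$testing$nonfatal_strokes) * n,
      fatal = (strategies$no_testing$fatal_strokes -
                 strategies$testing$fatal_strokes) * n)
  )
  class(res) <- "cea"
  res
}

fmt_gbp <- function(x) paste0(ifelse(x < 0, "-", ""), "£",
                              format(round(abs(x)), big.mark = ",",
                                     scientific = FALSE, trim = TRUE))

#' @export
print.cea <- function(x, ...) {
  cat("Cost-effectiveness of point-of-care CYP2C19 testing after ischaemic stroke\n")
  cat(sprintf("  %-28s %12s %12s\n", "Strategy", "Total cost", "Total QALYs"))
  for (s in names(x$strategies))
    cat(sprintf("  %-28s %12s %12.3f\n",
                c(no_testing = "No testing (clopidogrel)",
                  testing = "CYP2C19 testing")[[s]],
                fmt_gbp(x$strategies[[s]]$cost), x$strategies[[s]]$qalys))
  cat(sprintf("  Incremental (testing - no testing): cost %s, QALYs %.3f\n",
              fmt_gbp(x$delta_cost), x$delta_qaly))
  cat("  ICER:", if (is.character(x$icer)) paste0("not applicable - testing ",
                                                  x$icer)
      else fmt_gbp(x$icer), "\n")
  cat(sprintf("  NHB %.3f QALYs/patient, NMB %s/patient at lambda %s/QALY\n",
              x$nhb, fmt_gbp(x$nmb), fmt_gbp(x$params$lambda)))
  invisible(x)
}

#' @export
summary.cea <- function(object, ...) {
  structure(list(fit = object), class = "summary.cea")
}

#' @export
print.summary.cea <- function(x, ...) {
  f <- x$fit
  print(f)
  n <- f$params$cohort_size
  cat(sprintf("  Population (n = %s): total NHB %s QALYs, total NMB %s\n",
              format(n, big.mark = ","),
              format(round(f$nhb_total), big.mark = ","),
              fmt_gbp(f$nmb_total)))
  cat(sprintf("  Strokes prevented across cohort: %s non-fatal, %s fatal\n",
              format(round(f$strokes_prevented$nonfatal), big.mark = ","),
              format(round(f$strokes_prevented$fatal), big.mark = ",")))
  cat(sprintf("  Undiscounted life expectancy per patient: %.2f (testing) vs %.2f years\n",
              f$strategies$testing$life_years,
              f$strategies$no_testing$life_years))
  invisible(x)
}

#' Plot method for a fitted model: state occupancy over time
#'
#' Draws the alive-state occupancy curves of both strategies against age.
#'
#' @param x a `cea` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cea <- function(x, ...) {
  tr <- x$strategies
  ages <- x$params$start_age + 0:(nrow(tr$testing$trace$occupancy) - 1L)
  alive <- cbind(
    testing = rowSums(tr$testing$trace$occupancy[, 1:3]),
    no_testing = rowSums(tr$no_testing$trace$occupancy[, 1:3]))
  graphics::matplot(ages, alive, type = "l", lty = 1:2, col = c(2, 1),
                    xlab = "Age (years)", ylab = "Proportion alive",
                    main = "Cohort survival by strategy", ...)
  graphics::legend("topright", c("CYP2C19 testing", "No testing"),
                   lty = 1:2, col = c(2, 1), bty = "n")
  invisible(x)
}
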