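# Model inputs: a validated parameter set covering the decision tree,
# the Markov cohort model, the economic analysis and the PSA.

REGIMENS <- c("clopidogrel", "mrd_aspirin", "aspirin")
GENOTYPE_GROUPS <- c("noLoF", "LoF")

PARAM_SCHEMA_VERSION <- 1L

# Scalar fields with their admissible ranges (closed intervals; NA = unbounded).
.scalar_fields <- list(
  lof_prevalence                    = c(0, 1),
  rr_clopidogrel_noLoF              = c(0, NA),
  p_stroke_clopidogrel_avg          = c(0, 1),
  p_stroke_mrd_aspirin              = c(0, 1),
  p_stroke_aspirin                  = c(0, 1),
  fatal_stroke_fraction             = c(0, 1),
  disabling_fraction                = c(0, 1),
  tolerance_clopidogrel             = c(0, 1),
  tolerance_mrd                     = c(0, 1),
  test_cost                         = c(0, NA),
  staff_cost                        = c(0, NA),
  annual_cost_nondisabling          = c(0, NA),
  annual_cost_disabling             = c(0, NA),
  onecost_nondisabling              = c(0, NA),
  onecost_disabling                 = c(0, NA),
  onecost_fatal_stroke              = c(0, NA),
  onecost_nonstroke_death           = c(0, NA),
  utility_no_further_stroke         = c(0, 1),
  utility_decrement_per_stroke_state = c(0, 1),
  disutility_minor_bleed            = c(0, 1),
  disutility_major_bleed            = c(0, 1),
  disutility_chf                    = c(0, 1),
  discount_rate                     = c(0, NA),
  lambda                            = c(NA, NA),  # checked > 0 separately
  start_age                         = c(0, NA),
  max_age                           = c(0, NA),
  cohort_size                       = c(0, NA)
)

# Per-regimen fields (named numeric vectors over REGIMENS).
.regimen_fields <- list(
  drug_cost     = c(0, NA),
  ae_cost       = c(0, NA),
  p_minor_bleed = c(0, 1),
  p_major_bleed = c(0, 1),
  p_chf         = c(0, 1)
)

#' Default model parameters
#'
#' The default parameter set for the CYP2C19 test-and-treat model: a UK
#' cohort of first ischaemic strokes, mean entry age 67, lifetime horizon,
#' NHS perspective, 2021 prices, 3.5\% annual discounting and a
#' willingness-to-pay threshold of GBP 20,000 per QALY.  Published unit
#' costs and utilities are used where available; transition and tolerance
#' inputs without a published point estimate ship as documented assumptions
#' (see the package vignette) and can be overridden field by field.
#'
#' @param ... named overrides of any parameter field, e.g.
#'   `cea_params(test_cost = 100)`.  Per-regimen fields take a named vector
#'   over `c("clopidogrel", "mrd_aspirin", "aspirin")`.
#' @return A validated object of class `cea_params` (a named list).
#' @examples
#' p <- cea_params()
#' p$test_cost
#' cea_params(rr_clopidogrel_noLoF = 1)$rr_clopidogrel_noLoF
#' @export
cea_params <- function(...) {
  p <- .default_params()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("all overrides must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (nm in names(dots)) {
      if (nm %in% names(.regimen_fields)) {
        v <- unlist(dots[[nm]])
        if (is.null(names(v)) && length(v) == length(REGIMENS))
          names(v) <- REGIMENS
        p[[nm]][names(v)] <- v
      } else {
        p[[nm]] <- dots[[nm]]
      }
    }
  }
  validate_params(p)
}

.default_params <- function() {
  rg <- function(clopidogrel, mrd_aspirin, aspirin)
    c(clopidogrel = clopidogrel, mrd_aspirin = mrd_aspirin, aspirin = aspirin)
  structure(list(
    schema_version = PARAM_SCHEMA_VERSION,
    # genotype and treatment effect
    lof_prevalence = 0.25,
    rr_clopidogrel_noLoF = 0.702,
    # annual probabilities of recurrent stroke; the unstratified clopidogrel
    # value implies a 2.79% annual risk in non-carriers at RR 0.702, and the
    # alternative regimens are assumed to match unstratified clopidogrel
    p_stroke_clopidogrel_avg = 0.03974,
    p_stroke_mrd_aspirin = 0.03974,
    p_stroke_aspirin = 0.03974,
    # risk of a further stroke once in the one-additional-stroke state;
    # NULL means "same as the per-regimen first-recurrence risk"
    p_stroke_after_first_recurrence = NULL,
    fatal_stroke_fraction = 0.20,     # assumption: recurrent-stroke case fatality
    disabling_fraction = 0.50,        # assumption: non-fatal recurrences disabling
    tolerance_clopidogrel = 0.95,     # assumption: able to remain on clopidogrel
    tolerance_mrd = 0.90,             # assumption: able to remain on MRD+aspirin
    # testing costs (2021 GBP)
    test_cost = 60,
    staff_cost = 16.91,
    # state and event costs (2021 GBP)
    annual_cost_nondisabling = 2087,
    annual_cost_disabling = 6407,
    onecost_nondisabling = 7936,
    onecost_disabling = 16896,
    onecost_fatal_stroke = 10855,
    onecost_nonstroke_death = 2755,
    # per-regimen annual costs (2021 GBP)
    drug_cost = rg(32, 82, 22),
    ae_cost = rg(25, 32, 27),
    # per-regimen annual adverse-event probabilities (assumptions)
    p_minor_bleed = rg(0.030, 0.030, 0.030),
    p_major_bleed = rg(0.005, 0.004, 0.004),
    p_chf = rg(0.000, 0.006, 0.000),
    # utilities
    utility_no_further_stroke = 0.61,
    utility_decrement_per_stroke_state = 0.174,
    disutility_minor_bleed = 0.0033,
    disutility_major_bleed = 0.1426,
    disutility_chf = 0.0163,
    # economics and cohort
    discount_rate = 0.035,
    lambda = 20000,
    start_age = 67,
    max_age = 100,
    cohort_size = 60424,
    # PSA dispersion defaults (overridable per parameter; see ?psa_distributions)
    psa = list(cost_cv = 0.15, prob_se_frac = 0.10, rr_cv = 0.10,
               overrides = list())
  ), class = "cea_params")
}

#' Validate a parameter set
#'
#' Checks every invariant of the model inputs: probabilities, proportions and
#' utilities in \[0, 1\]; costs and the discount rate non-negative; a positive
#' willingness-to-pay threshold; `start_age < max_age`; per-regimen fields
#' complete over the three regimens.
#'
#' @param p a list of parameter fields (typically from [cea_params()] or
#'   [load_parameters()]).
#' @return `p` (classed `cea_params`), invisibly usable; errors name the
#'   offending field.
#' @export
validate_params <- function(p) {
  if (!is.list(p)) stop("parameters must be a list", call. = FALSE)
  need <- c("schema_version", names(.scalar_fields), names(.regimen_fields),
            "psa")
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  chk_scalar <- function(nm, x, rng) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      stop("field '", nm, "' must be a single non-missing number",
           call. = FALSE)
    if (!is.na(rng[1]) && x < rng[1])
      stop("field '", nm, "' = ", x, " below lower bound ", rng[1],
           call. = FALSE)
    if (!is.na(rng[2]) && x > rng[2])
      stop("field '", nm, "' = ", x, " above upper bound ", rng[2],
           call. = FALSE)
  }
  for (nm in names(.scalar_fields)) chk_scalar(nm, p[[nm]], .scalar_fields[[nm]])
  for (nm in names(.regimen_fields)) {
    v <- p[[nm]]
    if (!is.numeric(v) || !setequal(names(v), REGIMENS))
      stop("field '", nm, "' must be a named numeric vector over regimens ",
           paste(REGIMENS, collapse = ", "), call. = FALSE)
    for (r in REGIMENS) chk_scalar(paste0(nm, ".", r), v[[r]],
                                   .regimen_fields[[nm]])
    p[[nm]] <- v[REGIMENS]
  }
  if (!is.null(p$p_stroke_after_first_recurrence)) {
    v <- p$p_stroke_after_first_recurrence
    if (!is.numeric(v) || !setequal(names(v), REGIMENS))
      stop("field 'p_stroke_after_first_recurrence' must be NULL or a named ",
           "numeric vector over regimens", call. = FALSE)
    for (r in REGIMENS)
      chk_scalar(paste0("p_stroke_after_first_recurrence.", r), v[[r]], c(0, 1))
    p$p_stroke_after_first_recurrence <- v[REGIMENS]
  }
  if (p$lambda <= 0) stop("field 'lambda' must be > 0", call. = FALSE)
  if (p$start_age >= p$max_age)
    stop("field 'start_age' must be below 'max_age'", call. = FALSE)
  if (!is.list(p$psa))
    stop("field 'psa' must be a list", call. = FALSE)
  extra <- setdiff(names(p), c(need, "p_stroke_after_first_recurrence"))
  if (length(extra))
    stop("unknown parameter field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  # field order and storage types are normalised so save/load round-trips
  # bit-identically
  ord <- c("schema_version", names(.scalar_fields),
           "p_stroke_after_first_recurrence", names(.regimen_fields), "psa")
  p <- p[ord]
  names(p) <- ord  # a NULL optional field indexes with an NA name otherwise
  for (nm in c(names(.scalar_fields), names(.regimen_fields)))
    p[[nm]] <- as.numeric(stats::setNames(p[[nm]], names(p[[nm]])))
  for (nm in names(.regimen_fields)) names(p[[nm]]) <- REGIMENS
  if (!is.null(p$p_stroke_after_first_recurrence))
    p$p_stroke_after_first_recurrence <-
      stats::setNames(as.numeric(p$p_stroke_after_first_recurrence), REGIMENS)
  p$psa <- list(cost_cv = as.numeric(p$psa$cost_cv %||% 0.15),
                prob_se_frac = as.numeric(p$psa$prob_se_frac %||% 0.10),
                rr_cv = as.numeric(p$psa$rr_cv %||% 0.10),
                overrides = if (length(p$psa$overrides)) p$psa$overrides
                            else list())
  p$schema_version <- as.integer(p$schema_version)
  class(p) <- "cea_params"
  p
}

#' @export
print.cea_params <- function(x, ...) {
  cat("CYP2C19 test-and-treat model parameters (schema v",
      x$schema_version, ")\n", sep = "")
  cat(sprintf("  cohort: n = %s entering at age %d, horizon to age %d\n",
              format(x$cohort_size, big.mark = ","), x$start_age, x$max_age))
  cat(sprintf("  LoF prevalence %.3f; RR(no-LoF clopidogrel) %.3f; p(stroke|avg) %.5f\n",
              x$lof_prevalence, x$rr_clopidogrel_noLoF,
              x$p_stroke_clopidogrel_avg))
  cat(sprintf("  test cost £%.2f + staff £%.2f; discount %.1f%%; lambda £%s/QALY\n",
              x$test_cost, x$staff_cost, 100 * x$discount_rate,
              format(x$lambda, big.mark = ",")))
  invisible(x)
}

#' Read model parameters from file
#'
#' Reads a YAML parameter file conforming to the documented schema (see the
#' bundled default, `system.file("extdata", "parameters_default.yaml",
#' package = "strokepgx")`).  The file must carry a `schema_version` field;
#' an optional `assumptions` block holds inputs that are modelling
#' assumptions rather than published values and is merged into the parameter
#' set (a field may not appear in both places).  Unknown fields are rejected.
#'
#' @param path path to a YAML parameter file.
#' @return A validated `cea_params` object.
#' @seealso [save_parameters()], [cea_params()]
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed parameter file: ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(raw)) stop("malformed parameter file: not a mapping",
                          call. = FALSE)
  if (is.null(raw$schema_version))
    stop("parameter file lacks a 'schema_version' field", call. = FALSE)
  if (raw$schema_version != PARAM_SCHEMA_VERSION)
    stop("unsupported schema_version: ", raw$schema_version, call. = FALSE)
  if (!is.null(raw$assumptions)) {
    dup <- intersect(names(raw$assumptions), names(raw))
    if (length(dup))
      stop("field(s) defined both at top level and under 'assumptions': ",
           paste(dup, collapse = ", "), call. = FALSE)
    raw <- c(raw[names(raw) != "assumptions"], raw$assumptions)
  }
  for (nm in names(.regimen_fields))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  if (!is.null(raw$p_stroke_after_first_recurrence))
    raw$p_stroke_after_first_recurrence <-
      unlist(raw$p_stroke_after_first_recurrence)
  validate_params(raw)
}

#' Write model parameters to file
#'
#' Serialises a parameter set to YAML at full double precision, so that
#' `load_parameters(save_parameters(p, f))` reproduces `p` bit-identically.
#'
#' @param p a `cea_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(p, path) {
  p <- validate_params(p)
  out <- unclass(p)
  out$p_stroke_after_first_recurrence <-
    if (is.null(out$p_stroke_after_first_recurrence)) NULL else
      as.list(out$p_stroke_after_first_recurrence)
  for (nm in names(.regimen_fields)) out[[nm]] <- as.list(out[[nm]])
  writeLines(yaml::as.yaml(out, precision = 22L), path)
  invisible(path)
}

#' Derive the size of the modelled stroke cohort
#'
#' Applies a first-stroke incidence rate to a national population and keeps
#' the ischaemic fraction, rounding to the nearest whole person at each step.
#'
#' @param incidence_per_1000 annual first-stroke incidence per 1,000 people.
#' @param population population size.
#' @param ischaemic_fraction proportion of first strokes that are ischaemic.
#' @return A list with integer counts `first_strokes` and `ischaemic_strokes`.
#' @examples
#' estimate_population(1.07, 66436000, 0.85)
#' @export
estimate_population <- function(incidence_per_1000, population,
                                ischaemic_fraction) {
  if (incidence_per_1000 < 0 || population < 0)
    stop("incidence and population must be non-negative", call. = FALSE)
  if (ischaemic_fraction < 0 || ischaemic_fraction > 1)
    stop("ischaemic_fraction must lie in [0, 1]", call. = FALSE)
  first <- round(incidence_per_1000 / 1000 * population)
  isch <- round(ischaemic_fraction * first)
  list(first_strokes = as.integer(first), ischaemic_strokes = as.integer(isch))
}

#' Genotype-stratified stroke risks on clopidogrel
#'
#' The unstratified annual recurrent-stroke probability on clopidogrel is a
#' prevalence-weighted mixture of the risks in non-carriers and carriers of a
#' loss-of-function allele.  Given the population-average probability, the
#' risk ratio for non-carriers relative to the unstratified population, and
#' the carrier prevalence, this solves the mixture identity
#' \deqn{(1 - f)\,p_{noLoF} + f\,p_{LoF} = p_{avg}}
#' for the two group-specific probabilities.
#'
#' @param p_avg unstratified annual probability of recurrent stroke on
#'   clopidogrel.
#' @param rr_noLoF risk ratio for non-carriers vs the unstratified population.
#' @param f_lof prevalence of loss-of-function carriers, in (0, 1).
#' @return A list with annual probabilities `p_noLoF` and `p_LoF`.
#' @examples
#' derive_genotype_risks(0.03974, 0.702, 0.25)
#' @export
derive_genotype_risks <- function(p_avg, rr_noLoF, f_lof) {
  if (f_lof <= 0 || f_lof >= 1)
    stop("f_lof must lie strictly inside (0, 1)", call. = FALSE)
  if (rr_noLoF <= 0) stop("rr_noLoF must be positive", call. = FALSE)
  p_no <- rr_noLoF * p_avg
  p_lof <- p_avg * (1 - (1 - f_lof) * rr_noLoF) / f_lof
  tol <- 1e-12
  if (p_no < 0 || p_no > 1 + tol || p_lof < -tol || p_lof > 1 + tol)
    stop_infeasible("infeasible parameters: derived genotype-specific ",
                    "probability outside [0, 1]")
  list(p_noLoF = min(p_no, 1), p_LoF = min(max(p_lof, 0), 1))
}
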