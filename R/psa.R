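# Probabilistic sensitivity analysis.  Each uncertain parameter gets a
# distribution respecting its support -- beta for probabilities, proportions
# and utilities; gamma for costs; lognormal for the risk ratio -- with
# family parameters obtained by matching the point estimate and a dispersion
# (standard error, or a coefficient of variation for costs) by the method
# of moments.

# Parameters held fixed across PSA iterations (design settings, not
# epidemiological uncertainty).
.psa_fixed <- c("schema_version", "discount_rate", "lambda", "start_age",
                "max_age", "cohort_size")

#' Build the PSA distribution specification for a parameter set
#'
#' Maps every uncertain parameter to a distribution family and dispersion.
#' Defaults (overridable through `params$psa`): costs get a gamma
#' distribution with coefficient of variation `cost_cv` (0.15); probabilities,
#' proportions and utilities get a beta distribution with standard error
#' `prob_se_frac` (0.10) times the point estimate; the clopidogrel risk
#' ratio gets a lognormal with coefficient of variation `rr_cv` (0.10).
#' Parameters with point estimate 0 (nothing to scale a dispersion from) and
#' the design settings (discount rate, threshold, ages, cohort size) are held
#' fixed.  Per-parameter overrides live in `params$psa$overrides` as named
#' lists `list(family =, se =)`; family `"fixed"` pins a parameter.
#'
#' @param params a `cea_params` object.
#' @return A named list of specs, one per scalar parameter (per-regimen
#'   fields use dotted names, e.g. `"drug_cost.clopidogrel"`), each a list
#'   with `family` (`"beta"`, `"gamma"`, `"lognormal"` or `"fixed"`), `mean`
#'   and `se`.
#' @export
psa_distributions <- function(params) {
  params <- validate_params(params)
  cfg <- params$psa
  specs <- list()
  add <- function(name, mean, family, se) {
    if (family != "fixed" && (mean == 0 || se == 0)) family <- "fixed"
    specs[[name]] <<- list(family = family, mean = mean,
                           se = if (family == "fixed") 0 else se)
  }
  for (nm in names(.scalar_fields)) {
    if (nm %in% .psa_fixed) next
    m <- params[[nm]]
    if (nm == "rr_clopidogrel_noLoF") add(nm, m, "lognormal", cfg$rr_cv * m)
    else if (identical(.scalar_fields[[nm]], c(0, 1)))
      add(nm, m, "beta", cfg$prob_se_frac * m)
    else add(nm, m, "gamma", cfg$cost_cv * m)
  }
  for (nm in names(.regimen_fields)) {
    rng <- .regimen_fields[[nm]]
    for (r in REGIMENS) {
      m <- params[[nm]][[r]]
      key <- paste0(nm, ".", r)
      if (identical(rng, c(0, 1))) add(key, m, "beta", cfg$prob_se_frac * m)
      else add(key, m, "gamma", cfg$cost_cv * m)
    }
  }
  if (!is.null(params$p_stroke_after_first_recurrence))
    for (r in REGIMENS)
      add(paste0("p_stroke_after_first_recurrence.", r),
          params$p_stroke_after_first_recurrence[[r]], "beta",
          cfg$prob_se_frac * params$p_stroke_after_first_recurrence[[r]])
  for (nm in names(cfg$overrides)) {
    if (!nm %in% names(specs))
      stop("PSA override for unknown parameter '", nm, "'", call. = FALSE)
    ov <- cfg$overrides[[nm]]
    specs[[nm]]$family <- ov$family %||% specs[[nm]]$family
    specs[[nm]]$se <- ov$se %||% specs[[nm]]$se
    if (specs[[nm]]$family == "fixed" || specs[[nm]]$se == 0) {
      specs[[nm]]$family <- "fixed"; specs[[nm]]$se <- 0
    }
  }
  specs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Method-of-moments family parameters.
beta_moments <- function(mean, se) {
  if (mean <= 0 || mean >= 1)
    stop("beta moment matching needs mean strictly inside (0, 1)",
         call. = FALSE)
  if (se^2 >= mean * (1 - mean))
    stop("beta standard error ", se, " too large for mean ", mean,
         call. = FALSE)
  nu <- mean * (1 - mean) / se^2 - 1
  list(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

gamma_moments <- function(mean, cv_or_se) {
  se <- cv_or_se
  list(shape = mean^2 / se^2, rate = mean / se^2)
}

lnorm_moments <- function(mean, se) {
  cv2 <- (se / mean)^2
  sdlog <- sqrt(log(1 + cv2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

draw_one <- function(spec) {
  switch(spec$family,
    fixed = spec$mean,
    beta = {
      mm <- beta_moments(spec$mean, spec$se)
      stats::rbeta(1, mm$shape1, mm$shape2)
    },
    gamma = {
      mm <- gamma_moments(spec$mean, spec$se)
      stats::rgamma(1, shape = mm$shape, rate = mm$rate)
    },
    lognormal = {
      mm <- lnorm_moments(spec$mean, spec$se)
      stats::rlnorm(1, mm$meanlog, mm$sdlog)
    },
    stop("unknown distribution family '", spec$family, "'", call. = FALSE))
}

# Write a (possibly dotted) parameter name into a parameter set.
set_param <- function(params, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) params[[name]] <- value
  else params[[parts[1]]][[parts[2]]] <- value
  params
}

get_param <- function(params, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) params[[name]] else params[[parts[1]]][[parts[2]]]
}

# Deterministic per-iteration substream seed (order-independent), < 2^31.
derive_seed <- function(seed, iteration, attempt = 0L) {
  as.integer((as.double(seed) * 48271 + iteration * 10007 + attempt * 101 +
                1) %% 2147483629)
}

#' Draw one parameter set from the PSA distributions
#'
#' Samples every uncertain parameter independently from its specified
#' family, leaving fixed parameters at their point estimates.  The caller's
#' RNG state is left untouched; identical `(params, spec, seed)` give an
#' identical draw.
#'
#' @param params a `cea_params` object (the point estimates).
#' @param spec a distribution specification from [psa_distributions()].
#' @param seed integer seed for this draw.
#' @return A validated `cea_params` draw.
#' @export
sample_parameters <- function(params, spec = psa_distributions(params),
                              seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draw <- params
  for (nm in names(spec)) draw <- set_param(draw, nm, draw_one(spec[[nm]]))
  validate_params(draw)
}

#' Run the probabilistic sensitivity analysis
#'
#' Re-runs the full pipeline (sample parameters, allocate treatments, trace
#' the cohort, accumulate outcomes, incremental analysis) across
#' `n_iterations` independent draws.  Draws whose sampled parameters are
#' jointly infeasible (the mixture identity would imply a carrier stroke
#' probability outside \[0, 1\]) are resampled, up to `retry_limit` attempts
#' per iteration, and the number of resamples is recorded.  Each iteration
#' uses its own deterministically derived substream seed, so results do not
#' depend on execution order.
#'
#' @param params a `cea_params` object.
#' @param n_iterations number of PSA iterations (>= 1).
#' @param seed master integer seed.
#' @param life_table optional life table (default: synthetic Gompertz).
#' @param spec distribution specification (default
#'   [psa_distributions()] of `params`).
#' @param retry_limit maximum resampling attempts per iteration.
#' @return An object of class `cea_psa`: `draws` (a `data.frame` with one
#'   row per iteration: per-strategy cost and QALYs, `delta_cost`,
#'   `delta_qaly`, `nhb`, `nmb`), summary `means`, `p_cost_effective`
#'   (proportion of iterations with NMB > 0), `p_cost_saving` (proportion
#'   with incremental cost < 0), and bookkeeping fields.
#' @examples
#' ps <- run_psa(cea_params(), n_iterations = 10, seed = 1)
#' ps$p_cost_effective
#' @export
run_psa <- function(params, n_iterations, seed, life_table = NULL,
                    spec = NULL, retry_limit = 100L) {
  params <- validate_params(params)
  if (n_iterations < 1) stop("n_iterations must be at least 1", call. = FALSE)
  if (is.null(life_table))
    life_table <- generate_life_table(start_age = params$start_age,
                                      max_age = params$max_age)
  if (is.null(spec)) spec <- psa_distributions(params)
  cols <- c("cost_testing", "qalys_testing", "cost_no_testing",
            "qalys_no_testing", "delta_cost", "delta_qaly", "nhb", "nmb")
  draws <- matrix(NA_real_, n_iterations, length(cols),
                  dimnames = list(NULL, cols))
  resamples <- 0L
  for (i in seq_len(n_iterations)) {
    fit <- NULL
    for (attempt in 0:retry_limit) {
      d <- sample_parameters(params, spec, derive_seed(seed, i, attempt))
      fit <- tryCatch(cea(d, life_table),
                      strokepgx_infeasible = function(e) NULL)
      if (!is.null(fit)) break
      resamples <- resamples + 1L
    }
    if (is.null(fit))
      stop("iteration ", i, ": no feasible draw within ", retry_limit,
           " attempts", call. = FALSE)
    draws[i, ] <- c(fit$strategies$testing$cost,
                    fit$strategies$testing$qalys,
                    fit$strategies$no_testing$cost,
                    fit$strategies$no_testing$qalys,
                    fit$delta_cost, fit$delta_qaly, fit$nhb, fit$nmb)
  }
  draws <- as.data.frame(draws)
  structure(list(
    draws = draws,
    n_iterations = n_iterations,
    seed = seed,
    resamples = resamples,
    lambda = params$lambda,
    cohort_size = params$cohort_size,
    means = colMeans(draws),
    p_cost_effective = mean(draws$nmb > 0),
    p_cost_saving = mean(draws$delta_cost < 0)
  ), class = "cea_psa")
}

#' Simulate method: PSA draws from a fitted model
#'
#' `simulate()` on a fitted `cea` object runs the probabilistic sensitivity
#' analysis around the fit's parameter point estimates, reusing its life
#' table.
#'
#' @param object a `cea` object.
#' @param nsim number of PSA iterations.
#' @param seed master seed (required for reproducibility; defaults to 1).
#' @param ... passed on to [run_psa()] (e.g. `spec`).
#' @return A `cea_psa` object.
#' @examples
#' fit <- cea()
#' ps <- simulate(fit, nsim = 10, seed = 42)
#' @export
simulate.cea <- function(object, nsim = 1000, seed = 1, ...) {
  run_psa(object$params, n_iterations = nsim, seed = seed,
          life_table = object$life_table, ...)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value in the grid, the proportion of PSA
#' iterations in which the testing strategy has positive net monetary
#' benefit (`delta_qaly * lambda - delta_cost > 0`).  As lambda approaches
#' zero the curve approaches the probability of being cost-saving.
#'
#' @param psa a `cea_psa` object.
#' @param lambda_grid vector of positive willingness-to-pay values.
#' @return A `data.frame` with columns `lambda` and `probability`.
#' @export
ceac <- function(psa, lambda_grid = seq(1000, 50000, by = 1000)) {
  stopifnot(inherits(psa, "cea_psa"))
  if (length(lambda_grid) == 0 || any(lambda_grid <= 0))
    stop("lambda grid must be non-empty and strictly positive",
         call. = FALSE)
  prob <- vapply(lambda_grid, function(l)
    mean(psa$draws$delta_qaly * l - psa$draws$delta_cost > 0), numeric(1))
  data.frame(lambda = lambda_grid, probability = prob)
}

#' @export
print.cea_psa <- function(x, ...) {
  m <- x$means
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations (seed %s",
              x$n_iterations, format(x$seed)),
      if (x$resamples > 0) sprintf(", %d infeasible draws resampled)",
                                   x$resamples) else ")", "\n", sep = "")
  cat(sprintf("  Mean totals: testing %s / %.3f QALYs; no testing %s / %.3f QALYs\n",
              fmt_gbp(m[["cost_testing"]]), m[["qalys_testing"]],
              fmt_gbp(m[["cost_no_testing"]]), m[["qalys_no_testing"]]))
  cat(sprintf("  Mean incremental: cost %s, QALYs %.3f; NHB %.3f, NMB %s\n",
              fmt_gbp(m[["delta_cost"]]), m[["delta_qaly"]], m[["nhb"]],
              fmt_gbp(m[["nmb"]])))
  cat(sprintf("  P(cost-effective at lambda %s) = %.2f; P(cost-saving) = %.2f\n",
              fmt_gbp(x$lambda), x$p_cost_effective, x$p_cost_saving))
  invisible(x)
}

#' Plot a PSA: cost-effectiveness plane or acceptability curve
#'
#' @param x a `cea_psa` object.
#' @param type `"plane"` for the incremental cost-effectiveness plane (one
#'   point per iteration, threshold line at the model's lambda), or
#'   `"ceac"` for the acceptability curve.
#' @param lambda_grid grid for `type = "ceac"`.
#' @param ... passed to the underlying plot call.
#' @export
plot.cea_psa <- function(x, type = c("plane", "ceac"),
                         lambda_grid = seq(1000, 50000, by = 1000), ...) {
  type <- match.arg(type)
  if (type == "plane") {
    graphics::plot(x$draws$delta_qaly, x$draws$delta_cost, pch = 20,
                   col = grDevices::grey(0.4, 0.5),
                   xlab = "Incremental QALYs", ylab = "Incremental cost (£)",
                   main = "Cost-effectiveness plane", ...)
    graphics::abline(h = 0, v = 0, col = "grey60")
    graphics::abline(a = 0, b = x$lambda, lty = 2)
    graphics::points(mean(x$draws$delta_qaly), mean(x$draws$delta_cost),
                     pch = 4, cex = 1.5, col = 2, lwd = 2)
  } else {
    cc <- ceac(x, lambda_grid)
    graphics::plot(cc$lambda, cc$probability, type = "l", ylim = c(0, 1),
                   xlab = "Willingness to pay (£/QALY)",
                   ylab = "Probability cost-effective",
                   main = "Cost-effectiveness acceptability curve", ...)
    graphics::abline(v = x$lambda, lty = 2, col = "grey60")
  }
  invisible(x)
}
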