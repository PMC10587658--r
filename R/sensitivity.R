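# Deterministic one-way threshold analysis: vary one parameter, all others
# at their point estimates, until the testing strategy stops being
# cost-effective.  The boundary is per-patient NMB = 0, which coincides with
# ICER = lambda in the north-east quadrant and remains well defined where
# one strategy dominates.

#' Parameters available to the threshold search
#'
#' Any scalar model parameter, or a per-regimen element addressed as
#' `field.regimen` (e.g. `"drug_cost.mrd_aspirin"`), can be searched.
#'
#' @return Character vector of searchable parameter names.
#' @export
threshold_parameters <- function() {
  c(setdiff(names(.scalar_fields), c("start_age", "max_age", "cohort_size")),
    as.vector(outer(names(.regimen_fields), REGIMENS, paste, sep = ".")))
}

#' One-way threshold search
#'
#' Bisection on the per-patient net monetary benefit as a function of a
#' single parameter, holding everything else at its base-case value.  If the
#' NMB does not change sign between the bounds the result is reported as
#' `"none in range"` -- the parameter cannot overturn cost-effectiveness
#' anywhere in the searched interval.
#'
#' @param param_name one of [threshold_parameters()].
#' @param bounds length-2 numeric: the interval to search (within the
#'   parameter's support).
#' @param params base-case `cea_params`.
#' @param life_table optional life table (default: synthetic Gompertz).
#' @param lambda willingness-to-pay threshold (default: `params$lambda`).
#' @param tolerance convergence tolerance on |NMB| at the root, in GBP per
#'   patient (default 0.01).
#' @param max_iter maximum bisection steps (default 200).
#' @return An object of class `cea_threshold`: `parameter`, `baseline`,
#'   `bounds`, `threshold` (number, or `NA` with `status = "none in range"`),
#'   `nmb_at_threshold`, `direction` of NMB across the interval, `status`,
#'   `iterations`.
#' @examples
#' ts <- threshold_search("test_cost", c(0, 5000), cea_params())
#' ts
#' @export
threshold_search <- function(param_name, bounds, params = cea_params(),
                             life_table = NULL, lambda = NULL,
                             tolerance = 0.01, max_iter = 200L) {
  if (!param_name %in% threshold_parameters())
    stop("'", param_name, "' is not a searchable parameter; choose one of: ",
         paste(threshold_parameters(), collapse = ", "), call. = FALSE)
  if (length(bounds) != 2L || !is.numeric(bounds) || bounds[1] >= bounds[2])
    stop("bounds must be a numeric interval c(lower, upper) with lower < upper",
         call. = FALSE)
  params <- validate_params(params)
  if (is.null(lambda)) lambda <- params$lambda
  if (is.null(life_table))
    life_table <- generate_life_table(start_age = params$start_age,
                                      max_age = params$max_age)
  g <- function(x) {
    p <- validate_params(set_param(params, param_name, x))
    fit <- cea(p, life_table)
    nmb(fit$delta_qaly, fit$delta_cost, lambda)
  }
  lo <- bounds[1]; hi <- bounds[2]
  g_lo <- g(lo); g_hi <- g(hi)
  baseline <- get_param(params, param_name)
  direction <- if (g_hi < g_lo) "decreasing" else "increasing"
  if (sign(g_lo) == sign(g_hi)) {
    res <- list(parameter = param_name, baseline = baseline, bounds = bounds,
                threshold = NA_real_, nmb_at_threshold = NA_real_,
                direction = direction, status = "none in range",
                iterations = 0L)
    class(res) <- "cea_threshold"
    return(res)
  }
  it <- 0L
  g_mid <- NA_real_
  while (it < max_iter) {
    mid <- (lo + hi) / 2
    g_mid <- g(mid)
    it <- it + 1L
    if (abs(g_mid) <= tolerance) break
    if (sign(g_mid) == sign(g_lo)) {
      lo <- mid; g_lo <- g_mid
    } else {
      hi <- mid; g_hi <- g_mid
    }
  }
  res <- list(parameter = param_name, baseline = baseline, bounds = bounds,
              threshold = mid, nmb_at_threshold = g_mid,
              direction = direction,
              status = if (abs(g_mid) <= tolerance) "converged"
                       else "max iterations reached",
              iterations = it)
  class(res) <- "cea_threshold"
  res
}

#' @export
print.cea_threshold <- function(x, ...) {
  cat("One-way threshold analysis on '", x$parameter, "'\n", sep = "")
  cat(sprintf("  baseline %.6g, searched [%.6g, %.6g], NMB %s in parameter\n",
              x$baseline, x$bounds[1], x$bounds[2], x$direction))
  if (x$status == "none in range")
    cat("  cost-effectiveness unchanged across the interval: none in range\n")
  else
    cat(sprintf("  threshold value %.6g (NMB %.4f at threshold; %d bisection steps)\n",
                x$threshold, x$nmb_at_threshold, x$iterations))
  invisible(x)
}
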