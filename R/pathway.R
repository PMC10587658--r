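# Decision tree: maps a strategy (point-of-care CYP2C19 testing vs current
# prescribing) to the fraction of the cohort on each antiplatelet regimen,
# split by genotype group, with tolerance cascades resolved once at entry.

STRATEGIES <- c("no_testing", "testing")

#' Allocate the cohort to antiplatelet regimens
#'
#' Resolves the prescribing decision tree for one strategy.  Under testing,
#' patients with no loss-of-function (LoF) allele receive clopidogrel,
#' cascading to modified-release dipyridamole plus aspirin (MRD+aspirin) and
#' then aspirin alone if the preceding drug is not tolerated; LoF carriers
#' skip clopidogrel and start the cascade at MRD+aspirin.  Under no testing
#' the genotype is unknown and every patient enters the clopidogrel cascade.
#' Tolerance is resolved once at model entry.  The testing strategy carries
#' an up-front per-patient cost of the test plus the staff time to run it.
#'
#' @param strategy `"testing"` or `"no_testing"`.
#' @param params a `cea_params` object.
#' @param test_failure_rate fraction of tests that fail to return a result,
#'   in which case the patient is treated as untested (default 0).
#' @return An object of class `cea_allocation`: a `data.frame` with columns
#'   `group` (`"noLoF"`/`"LoF"`), `regimen` and `fraction` (summing to 1 over
#'   all rows), with attributes `strategy` and `upfront_cost`.
#' @examples
#' allocate_treatments("testing", cea_params())
#' @export
allocate_treatments <- function(strategy, params, test_failure_rate = 0) {
  strategy <- as.character(strategy)
  if (length(strategy) != 1L || !strategy %in% STRATEGIES)
    stop("unknown strategy '", strategy, "'; expected one of: ",
         paste(STRATEGIES, collapse = ", "), call. = FALSE)
  if (test_failure_rate < 0 || test_failure_rate > 1)
    stop("test_failure_rate must lie in [0, 1]", call. = FALSE)
  f <- params$lof_prevalence
  tc <- params$tolerance_clopidogrel
  tm <- params$tolerance_mrd
  clop_cascade <- c(clopidogrel = tc,
                    mrd_aspirin = (1 - tc) * tm,
                    aspirin     = (1 - tc) * (1 - tm))
  lof_cascade <- c(clopidogrel = 0,
                   mrd_aspirin = tm,
                   aspirin     = 1 - tm)
  if (strategy == "no_testing") {
    per_group <- list(noLoF = clop_cascade, LoF = clop_cascade)
    upfront <- 0
  } else {
    fr <- test_failure_rate  # failed tests fall back to untested prescribing
    per_group <- list(
      noLoF = clop_cascade,
      LoF   = (1 - fr) * lof_cascade + fr * clop_cascade
    )
    upfront <- params$test_cost + params$staff_cost
  }
  alloc <- data.frame(
    group    = rep(GENOTYPE_GROUPS, each = length(REGIMENS)),
    regimen  = rep(REGIMENS, times = length(GENOTYPE_GROUPS)),
    fraction = c((1 - f) * per_group$noLoF, f * per_group$LoF),
    stringsAsFactors = FALSE
  )
  structure(alloc, strategy = strategy, upfront_cost = upfront,
            class = c("cea_allocation", "data.frame"))
}

#' @export
print.cea_allocation <- function(x, ...) {
  cat("Treatment allocation, strategy:", attr(x, "strategy"),
      sprintf("(up-front cost per patient: £%.2f)\n", attr(x, "upfront_cost")))
  print.data.frame(x[x$fraction > 0, ], row.names = FALSE, ...)
  invisible(x)
}

#' Write an allocation as delimited text
#'
#' @param alloc a `cea_allocation`.
#' @param path output path (tab-separated, with header).
#' @return `path`, invisibly.
#' @export
save_allocation <- function(alloc, path) {
  utils::write.table(as.data.frame(alloc), path, quote = FALSE,
                     row.names = FALSE, sep = "\t")
  invisible(path)
}
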