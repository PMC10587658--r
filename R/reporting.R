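# Run orchestration and result serialisation.  Each report function loads
# inputs from file, runs the analysis through the package functions, writes
# delimited-text outputs plus a human-readable summary, and records a run
# manifest (command, input hashes, seeds, package version, timestamp,
# outputs).  Numeric payloads are written at full precision so identical
# inputs give byte-identical numeric output files.

fmt_num <- function(x) vapply(x, function(v)
  formatC(v, digits = 17, format = "g"), character(1))

write_manifest <- function(dir, command, inputs, seed = NULL, n = NULL,
                           outputs) {
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("strokepgx")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    inputs = lapply(inputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    seed = seed, n = n,
    outputs = outputs
  )
  path <- file.path(dir, "manifest.yaml")
  writeLines(yaml::as.yaml(manifest), path)
  invisible(path)
}

load_inputs <- function(params_path, life_table_path) {
  params <- load_parameters(params_path)
  life_table <- if (is.null(life_table_path))
    generate_life_table(start_age = params$start_age,
                        max_age = params$max_age)
  else load_life_table(life_table_path)
  list(params = params, life_table = life_table)
}

#' Base-case analysis report
#'
#' Loads a parameter file (and optional life table), runs [cea()], and
#' writes to `out_dir`: `base_case.tsv` (per-strategy totals, incremental
#' results, dominance label, per-patient and population NHB/NMB, strokes
#' prevented), `report.txt` (human-readable), per-strategy traces and
#' allocations, and `manifest.yaml`.
#'
#' @param params_path path to a YAML parameter file.
#' @param life_table_path optional path to a life-table file; default uses
#'   the synthetic Gompertz table.
#' @param out_dir output directory (created if missing).
#' @return The fitted `cea` object, invisibly.
#' @export
run_report <- function(params_path, life_table_path = NULL, out_dir) {
  inp <- load_inputs(params_path, life_table_path)
  fit <- cea(inp$params, inp$life_table)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- data.frame(
    quantity = c("cost_testing", "qalys_testing", "cost_no_testing",
                 "qalys_no_testing", "delta_cost", "delta_qaly", "icer",
                 "nhb_per_patient", "nmb_per_patient", "nhb_total",
                 "nmb_total", "nonfatal_strokes_prevented",
                 "fatal_strokes_prevented"),
    units = c("GBP2021", "QALY", "GBP2021", "QALY", "GBP2021", "QALY",
              "GBP2021_per_QALY", "QALY", "GBP2021", "QALY", "GBP2021",
              "count", "count"),
    value = c(fmt_num(c(fit$strategies$testing$cost,
                        fit$strategies$testing$qalys,
                        fit$strategies$no_testing$cost,
                        fit$strategies$no_testing$qalys,
                        fit$delta_cost, fit$delta_qaly)),
              if (is.character(fit$icer)) fit$icer else fmt_num(fit$icer),
              fmt_num(c(fit$nhb, fit$nmb, fit$nhb_total, fit$nmb_total,
                        fit$strokes_prevented$nonfatal,
                        fit$strokes_prevented$fatal))),
    rounding = c(rep("unrounded", 13)),
    stringsAsFactors = FALSE
  )
  base_path <- file.path(out_dir, "base_case.tsv")
  utils::write.table(rows, base_path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  report_path <- file.path(out_dir, "report.txt")
  con <- file(report_path, "w"); sink(con)
  print(summary(fit)); sink(); close(con)
  outputs <- c(base_path, report_path)
  for (s in names(fit$strategies)) {
    tp <- file.path(out_dir, paste0("trace_", s, ".tsv"))
    save_trace(fit$strategies[[s]]$trace, tp)
    ap <- file.path(out_dir, paste0("allocation_", s, ".tsv"))
    save_allocation(fit$strategies[[s]]$allocation, ap)
    outputs <- c(outputs, tp, ap)
  }
  write_manifest(out_dir, "run",
                 c(list(params_path),
                   if (!is.null(life_table_path)) list(life_table_path)),
                 outputs = outputs)
  invisible(fit)
}

#' Probabilistic sensitivity analysis report
#'
#' Runs [run_psa()] from a parameter file and writes to `out_dir`:
#' `plane.tsv` (one row per iteration: incremental cost, incremental QALYs,
#' NHB, NMB), `ceac.tsv` (willingness-to-pay grid and probability
#' cost-effective), `psa_summary.tsv`, and `manifest.yaml` recording `n` and
#' `seed`.
#'
#' @inheritParams run_report
#' @param n number of PSA iterations (>= 1).
#' @param seed master seed.
#' @return The `cea_psa` object, invisibly.
#' @export
psa_report <- function(params_path, n, seed, life_table_path = NULL,
                       out_dir) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  inp <- load_inputs(params_path, life_table_path)
  ps <- run_psa(inp$params, n_iterations = n, seed = seed,
                life_table = inp$life_table)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  plane <- data.frame(iteration = seq_len(n),
                      delta_cost = fmt_num(ps$draws$delta_cost),
                      delta_qaly = fmt_num(ps$draws$delta_qaly),
                      nhb = fmt_num(ps$draws$nhb),
                      nmb = fmt_num(ps$draws$nmb))
  plane_path <- file.path(out_dir, "plane.tsv")
  utils::write.table(plane, plane_path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  cc <- ceac(ps)
  ceac_path <- file.path(out_dir, "ceac.tsv")
  utils::write.table(data.frame(lambda = cc$lambda,
                                probability = fmt_num(cc$probability)),
                     ceac_path, quote = FALSE, row.names = FALSE, sep = "\t")
  summ <- data.frame(quantity = c(names(ps$means), "p_cost_effective",
                                  "p_cost_saving", "resamples"),
                     value = fmt_num(c(unname(ps$means), ps$p_cost_effective,
                                       ps$p_cost_saving, ps$resamples)))
  summ_path <- file.path(out_dir, "psa_summary.tsv")
  utils::write.table(summ, summ_path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  write_manifest(out_dir, "psa",
                 c(list(params_path),
                   if (!is.null(life_table_path)) list(life_table_path)),
                 seed = seed, n = n,
                 outputs = c(plane_path, ceac_path, summ_path))
  invisible(ps)
}

#' Threshold analysis report
#'
#' Runs [threshold_search()] from a parameter file and writes
#' `threshold.tsv` (parameter, baseline, bounds, threshold or
#' `none in range`, NMB at threshold) and `manifest.yaml`.
#'
#' @inheritParams run_report
#' @param param_name parameter to search (see [threshold_parameters()]).
#' @param bounds numeric interval to search.
#' @return The `cea_threshold` object, invisibly.
#' @export
threshold_report <- function(params_path, param_name, bounds,
                             life_table_path = NULL, out_dir) {
  inp <- load_inputs(params_path, life_table_path)
  ts <- threshold_search(param_name, bounds, inp$params, inp$life_table)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  row <- data.frame(
    parameter = ts$parameter,
    baseline = fmt_num(ts$baseline),
    lower = fmt_num(ts$bounds[1]), upper = fmt_num(ts$bounds[2]),
    threshold = if (is.na(ts$threshold)) "none in range"
                else fmt_num(ts$threshold),
    nmb_at_threshold = if (is.na(ts$nmb_at_threshold)) ""
                       else fmt_num(ts$nmb_at_threshold),
    status = ts$status)
  path <- file.path(out_dir, "threshold.tsv")
  utils::write.table(row, path, quote = FALSE, row.names = FALSE, sep = "\t")
  write_manifest(out_dir, "threshold",
                 c(list(params_path),
                   if (!is.null(life_table_path)) list(life_table_path)),
                 outputs = path)
  invisible(ts)
}
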