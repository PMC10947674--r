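# Tabular reports: per-scenario trajectory tables, difference tables with
# uncertainty intervals and case counts, stratified tables, and a JSON run
# manifest. File contents are deterministic for fixed inputs.

#' Write report tables from replicate summaries
#'
#' Emits `trajectories.csv` (per-scenario medians and UIs of the overall
#' metrics), `differences.csv` (scenario minus baseline with UIs; CMD
#' prevalence differences carry a national case-count column computed by
#' [cases_from_pp()]), `stratified.csv` (subgroup rows) and
#' `manifest.json` (seed, mode, replicate count, package version).
#'
#' @param summaries output of [summarize_replicates()] (may be empty).
#' @param dir output directory (created if needed).
#' @param manifest named list of run metadata to record.
#' @return invisible character vector of file paths written.
#' @export
report_tables <- function(summaries, dir, manifest = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_domain("report_tables: cannot create ", dir)
  empty <- nrow(summaries) == 0
  overall <- if (empty) summaries else {
    summaries[summaries$subgroup_type == "overall", ]
  }
  strat <- if (empty) summaries else {
    summaries[summaries$subgroup_type != "overall", ]
  }
  traj_cols <- c("scenario", "year", "metric", "median", "lower", "upper",
                 "n_replicates")
  paths <- c(
    trajectories = file.path(dir, "trajectories.csv"),
    differences = file.path(dir, "differences.csv"),
    stratified = file.path(dir, "stratified.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_csv <- function(d, p) {
    utils::write.csv(d, p, row.names = FALSE, quote = FALSE)
  }
  write_csv(overall[, intersect(traj_cols, names(overall)), drop = FALSE],
            paths["trajectories"])

  diff_cols <- c("scenario", "year", "metric", "diff_median", "diff_lower",
                 "diff_upper", "diff_of_medians")
  diffs <- if (empty || !"diff_median" %in% names(overall)) {
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(diff_cols) + 3)),
                    c(diff_cols, "cases", "cases_lower", "cases_upper"))
  } else {
    d <- overall[overall$scenario != "baseline" & is.finite(overall$diff_median),
                 diff_cols, drop = FALSE]
    is_cmd <- d$metric == "cmd_pct"
    d$cases <- d$cases_lower <- d$cases_upper <- NA_real_
    d$cases[is_cmd] <- cases_from_pp(d$diff_median[is_cmd])
    d$cases_lower[is_cmd] <- cases_from_pp(d$diff_lower[is_cmd])
    d$cases_upper[is_cmd] <- cases_from_pp(d$diff_upper[is_cmd])
    d
  }
  write_csv(diffs, paths["differences"])
  write_csv(strat, paths["stratified"])
  jsonlite::write_json(c(manifest, list(package = "ubisim",
                                        version = "0.1.0")),
                       paths["manifest"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
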