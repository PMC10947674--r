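# Replicate engine: repeat the full pipeline with fresh parameter draws and
# random streams; summarise metrics as medians with 95% uncertainty
# intervals from the 2.5th/97.5th percentiles.

#' Run uncertainty replicates
#'
#' Replicate `r` uses a seed derived deterministically from
#' `(base_seed, r)`, draws a fresh parameter set and population, runs all
#' configured scenarios with common random numbers, and records the
#' scenario-year metric rows. Results are independent of execution order.
#'
#' @param config a `ubi_run_config` or generator config.
#' @param n_reps number of replicates (>= 1).
#' @param base_seed integer base seed.
#' @param scenarios,mode,years as in [run_all()] (ignored when `config` is a
#'   full run config).
#' @param subgroup stratifications recorded per scenario-year (see
#'   [rates()]).
#' @param redraw_population draw a fresh population per replicate (default)
#'   or hold it fixed at the base seed's population.
#' @return data frame of metric rows with `replicate` and `rii`/`sii`
#'   columns appended per scenario-year, of class `ubi_replicates`.
#' @export
run_replicates <- function(config, n_reps, base_seed = 1L,
                           scenarios = c("baseline", "partial", "full", "full_plus"),
                           mode = "primary", years = 2022:2026,
                           subgroup = "all", redraw_population = TRUE) {
  if (n_reps < 1) stop_domain("run_replicates: n_reps must be >= 1")
  if (inherits(config, "ubi_run_config")) {
    scenarios <- config$scenarios; mode <- config$mode; years <- config$years
  }
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- if (redraw_population) derive_seed(base_seed, r) else base_seed
    par_seed <- derive_seed(base_seed, r)
    gen <- if (inherits(config, "ubi_run_config")) config$generator else config
    variant <- switch(mode, sens2_inactivity = "inactivity",
                      sens3_sysrev = "systematic_review", "primary")
    params <- draw_parameter_set(gen, derive_seed(par_seed, 101L), variant)
    pop <- generate_population(gen, derive_seed(rep_seed, 102L))
    run_seed <- derive_seed(par_seed, 103L)
    panels <- run_all_panels(pop, params, scenarios, mode, years, run_seed)
    rows <- replicate_metrics(panels, years, subgroup)
    rows$replicate <- r
    out[[r]] <- rows
  }
  res <- do.call(rbind, out)
  class(res) <- c("ubi_replicates", class(res))
  res
}

# run_all with a pre-built population and parameter set (shared plumbing for
# run_replicates; run_all() generates both internally).
run_all_panels <- function(pop, params, scenarios, mode, years, run_seed) {
  if (!"baseline" %in% scenarios) scenarios <- c("baseline", scenarios)
  panels <- list()
  panels$baseline <- run_scenario(pop, load_scenario("baseline"), years,
                                  params, run_seed)
  lines <- attr(panels$baseline, "poverty_lines")
  sens1_targets <- NULL
  if (mode == "sens1_fixed_employment") {
    base <- panels$baseline
    tgt <- vapply(years, function(y) {
      sub <- base[base$year == y & base$in_scope, ]
      mean(sub$employed)
    }, numeric(1))
    sens1_targets <- as.list(stats::setNames(tgt, years))
  }
  for (sc in setdiff(scenarios, "baseline")) {
    use_sens1 <- !is.null(sens1_targets) && sc %in% c("full", "full_plus")
    panels[[sc]] <- run_scenario(pop, load_scenario(sc), years, params,
                                 run_seed, poverty_lines = lines,
                                 sens1_targets = if (use_sens1) sens1_targets)
  }
  panels
}

replicate_metrics <- function(panels, years, subgroup) {
  rows <- list()
  for (sc in names(panels)) {
    for (y in years) {
      m <- rates(panels[[sc]], y, subgroup)
      ineq <- panel_rii(panels[[sc]], y)
      m <- rbind(m, data.frame(
        scenario = sc, year = y, subgroup_type = "overall",
        subgroup = "overall", metric = c("cmd_rii", "cmd_sii"),
        value = c(ineq$rii, ineq$sii), stringsAsFactors = FALSE))
      rows[[paste(sc, y)]] <- m
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median and 95% uncertainty interval of replicate values
#'
#' Median plus 2.5th and 97.5th percentiles by linear interpolation of the
#' order statistics (index = (n-1)p + 1, the default sample-quantile
#' convention).
#'
#' @param values numeric vector (>= 1 finite value).
#' @return list with `median`, `lower`, `upper`, `n`.
#' @export
ui_summarize <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop_domain("ui_summarize: no finite values")
  q <- stats::quantile(values, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
  list(median = q[2], lower = q[1], upper = q[3], n = length(values))
}

#' Uncertainty summary of scenario-minus-baseline differences
#'
#' In paired mode (the default; appropriate under common random numbers)
#' the per-replicate differences are summarised by [ui_summarize()]; the
#' difference of the two medians is also reported.
#'
#' @param scenario_values,baseline_values equal-length replicate-aligned
#'   vectors.
#' @param paired summarise per-replicate differences (`TRUE`) or only the
#'   difference of medians with percentile bounds from the unpaired
#'   distributions (`FALSE`).
#' @return list with `median`, `lower`, `upper`, `n`,
#'   `difference_of_medians`.
#' @export
summarize_difference <- function(scenario_values, baseline_values,
                                 paired = TRUE) {
  if (length(scenario_values) != length(baseline_values)) {
    stop_domain("summarize_difference: replicate vectors differ in length")
  }
  dom <- ui_summarize(scenario_values)$median - ui_summarize(baseline_values)$median
  out <- if (paired) {
    ui_summarize(scenario_values - baseline_values)
  } else {
    s <- ui_summarize(scenario_values); b <- ui_summarize(baseline_values)
    list(median = dom, lower = s$lower - b$upper, upper = s$upper - b$lower,
         n = s$n)
  }
  out$difference_of_medians <- dom
  out
}

#' Summarise replicate metric rows
#'
#' Collapses a `ubi_replicates` table to one row per
#' (scenario, year, subgroup, metric) with median and 95% UI; optionally
#' also the paired difference against baseline.
#'
#' @param reps table from [run_replicates()].
#' @param difference also compute paired differences versus baseline.
#' @return data frame of summaries (and differences when requested, in
#'   columns prefixed `diff_`).
#' @export
summarize_replicates <- function(reps, difference = TRUE) {
  key <- interaction(reps$scenario, reps$year, reps$subgroup_type,
                     reps$subgroup, reps$metric, drop = TRUE)
  pieces <- split(reps, key)
  out <- lapply(pieces, function(d) {
    s <- ui_summarize(d$value)
    data.frame(scenario = d$scenario[1], year = d$year[1],
               subgroup_type = d$subgroup_type[1], subgroup = d$subgroup[1],
               metric = d$metric[1], median = s$median, lower = s$lower,
               upper = s$upper, n_replicates = s$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out <- out[order(out$scenario, out$year, out$subgroup_type, out$subgroup,
                   out$metric), ]
  if (!difference) return(out)
  base <- reps[reps$scenario == "baseline", ]
  bkey <- function(d) paste(d$year, d$subgroup_type, d$subgroup, d$metric,
                            d$replicate, sep = "\r")
  base_lookup <- stats::setNames(base$value, bkey(base))
  diff_cols <- matrix(NA_real_, nrow(out), 4,
                      dimnames = list(NULL, c("diff_median", "diff_lower",
                                              "diff_upper",
                                              "diff_of_medians")))
  for (i in seq_len(nrow(out))) {
    if (out$scenario[i] == "baseline") next
    d <- reps[reps$scenario == out$scenario[i] & reps$year == out$year[i] &
                reps$subgroup_type == out$subgroup_type[i] &
                reps$subgroup == out$subgroup[i] &
                reps$metric == out$metric[i], ]
    b <- base_lookup[paste(d$year, d$subgroup_type, d$subgroup, d$metric,
                           d$replicate, sep = "\r")]
    if (all(is.finite(b)) && all(is.finite(d$value))) {
      s <- summarize_difference(d$value, as.numeric(b))
      diff_cols[i, ] <- c(s$median, s$lower, s$upper, s$difference_of_medians)
    }
  }
  cbind(out, as.data.frame(diff_cols))
}
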