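# Reported metrics from a panel: rates and prevalences (overall and
# stratified), relative/slope indices of inequality by education, and
# prevalence-to-case-count conversion for the UK working-age population.

#' UK working-age population size used for case-count conversion
#'
#' OECD estimate for Quarter 4 of 2022.
#' @export
uk_working_age_population <- 41566000

metric_names <- c("employment_pct", "poverty_pct", "median_income",
                  "mean_hours", "cmd_pct", "mean_ghq")

subgroup_defs <- function(df) {
  list(
    overall = list(overall = rep(TRUE, nrow(df))),
    gender = list(male = df$gender == "male", female = df$gender == "female"),
    education = list(high = df$education == "high",
                     medium = df$education == "medium",
                     low = df$education == "low"),
    age_band = list(`25-44` = df$age <= 44, `45-64` = df$age >= 45),
    children = list(has_children = df$has_children,
                    no_children = !df$has_children),
    lone_parent = list(lone_parent = df$lone_parent,
                       not_lone_parent = !df$lone_parent)
  )
}

#' Scenario-year outcome rates
#'
#' Employment (% of adults with positive hours), poverty (% below the
#' line), median income (benefit-unit disposable income per adult), mean
#' weekly hours, CMD prevalence (%) and mean GHQ Likert score, computed
#' over in-scope adults (25-64) of the requested subgroup(s). Empty strata
#' yield explicit `NA` values rather than silent zeros.
#'
#' @param panel a panel from [run_scenario()].
#' @param year single year present in the panel.
#' @param subgroup `"overall"`, one of `"gender"`, `"education"`,
#'   `"age_band"`, `"children"`, `"lone_parent"`, or `"all"` for every
#'   stratification.
#' @return tidy data frame: scenario, year, subgroup_type, subgroup,
#'   metric, value.
#' @export
rates <- function(panel, year, subgroup = "overall") {
  if (!year %in% panel$year) stop_domain("rates: year ", year, " not in panel")
  df <- panel[panel$year == year & panel$in_scope, ]
  defs <- subgroup_defs(df)
  types <- if (identical(subgroup, "all")) names(defs) else subgroup
  bad <- setdiff(types, names(defs))
  if (length(bad)) stop_domain("rates: unknown subgroup '", bad[1], "'")
  rows <- list()
  for (ty in types) {
    for (g in names(defs[[ty]])) {
      sub <- df[defs[[ty]][[g]], ]
      vals <- if (nrow(sub) == 0) {
        rep(NA_real_, length(metric_names))
      } else {
        c(100 * mean(sub$employed),
          100 * mean(sub$in_poverty),
          stats::median(sub$disposable_income),
          mean(sub$hours),
          100 * mean(sub$cmd),
          mean(sub$ghq_likert))
      }
      rows[[paste(ty, g)]] <- data.frame(
        scenario = panel$scenario[1] %||% NA_character_, year = year,
        subgroup_type = ty, subgroup = g, metric = metric_names,
        value = vals, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative and slope indices of inequality
#'
#' Groups are ranked most to least educated; each group's ridit midpoint is
#' the cumulative share of strictly higher-ranked groups plus half its own
#' share (so x = 0 is the hypothetically most-educated extreme). Prevalence
#' is regressed on the midpoints by weighted least squares with the shares
#' as weights. SII is the slope (fitted difference between the extremes);
#' RII is fitted(1)/fitted(0).
#'
#' @param groups data frame ordered most to least educated, with columns
#'   `share` (summing to 1) and `prevalence`.
#' @return list with `rii`, `sii`, `fitted0`, `fitted1`. When the fitted
#'   value at the most-educated extreme is not positive, RII is undefined
#'   and returned as `NA` with a warning (SII is still returned).
#' @export
rii_sii <- function(groups) {
  if (nrow(groups) < 2) stop_domain("rii_sii: need at least 2 groups")
  if (abs(sum(groups$share) - 1) > 1e-9) {
    stop_domain("rii_sii: shares must sum to 1")
  }
  x <- cumsum(groups$share) - groups$share / 2
  fit <- stats::lm(prevalence ~ x, data = cbind(groups, x = x),
                   weights = groups$share)
  b <- stats::coef(fit)
  f0 <- unname(b[1])
  f1 <- unname(b[1] + b[2])
  rii <- if (f0 <= 0) {
    warning("rii_sii: fitted prevalence at the most-educated extreme is not ",
            "positive; RII undefined", call. = FALSE)
    NA_real_
  } else f1 / f0
  list(rii = rii, sii = unname(b[2]), fitted0 = f0, fitted1 = f1)
}

#' CMD inequality indices from a panel
#'
#' Convenience wrapper: education-group shares and CMD prevalences for a
#' scenario-year (in-scope adults), passed to [rii_sii()].
#'
#' @inheritParams rates
#' @param outcome panel column to use as the binary outcome.
#' @return as [rii_sii()].
#' @export
panel_rii <- function(panel, year, outcome = "cmd") {
  df <- panel[panel$year == year & panel$in_scope, ]
  lev <- c("high", "medium", "low")    # most to least educated
  share <- vapply(lev, function(e) mean(df$education == e), numeric(1))
  prev <- vapply(lev, function(e) mean(df[[outcome]][df$education == e]),
                 numeric(1))
  rii_sii(data.frame(group = lev, share = share, prevalence = prev))
}

#' Convert a prevalence difference to a national case count
#'
#' Scales a difference in prevalence (percentage points) to the UK
#' working-age population and rounds to the nearest whole case.
#'
#' @param prevalence_difference_pp difference in percentage points.
#' @param population_size population to scale to (default the Q4-2022 UK
#'   working-age population, 41,566,000).
#' @return signed integer-valued case count.
#' @export
cases_from_pp <- function(prevalence_difference_pp,
                          population_size = uk_working_age_population) {
  if (any(!is.finite(prevalence_difference_pp))) {
    stop_domain("cases_from_pp: non-finite input")
  }
  round(prevalence_difference_pp / 100 * population_size)
}

#' Difference of metric tables between a scenario and baseline
#'
#' Elementwise differences matched on (year, subgroup_type, subgroup,
#' metric); a key present on one side only is an error.
#'
#' @param scenario_rows,baseline_rows tidy metric tables from [rates()].
#' @return tidy table of differences (`value` = scenario - baseline).
#' @export
scenario_difference <- function(scenario_rows, baseline_rows) {
  key <- function(d) paste(d$year, d$subgroup_type, d$subgroup, d$metric,
                           sep = "\r")
  ks <- key(scenario_rows); kb <- key(baseline_rows)
  if (length(ks) != length(kb) || !setequal(ks, kb) ||
      anyDuplicated(ks) || anyDuplicated(kb)) {
    stop_domain("scenario_difference: metric keys do not match")
  }
  m <- match(ks, kb)
  out <- scenario_rows
  out$value <- scenario_rows$value - baseline_rows$value[m]
  out$baseline_value <- baseline_rows$value[m]
  out
}
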