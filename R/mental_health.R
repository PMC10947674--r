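# Two-step causal mental-health module. Step 1 (demographic baseline CMD
# probability) lives in population.R; this file implements Step 2: economic
# transition detection and gender-specific additive risk differences on the
# probability scale, realised as a binary CMD flag (GHQ-12 caseness >= 4)
# and a parallel continuous GHQ Likert score (0-36).

#' Detect economic transitions between consecutive years
#'
#' Entry = not in state last year and in state now; exit = the reverse;
#' persistent = in state in both the current and previous year (2
#' consecutive years). Income change is measured on the log scale with
#' incomes floored at a configurable positive minimum. With no prior-year
#' state (`prev = NULL`), only the income-change channel is computed and
#' `has_lag` is `FALSE`.
#'
#' @param prev,cur lists/data frames with logical `in_poverty`, `employed`
#'   and numeric `income` (vectorised); `prev` may be `NULL`.
#' @param prev2 previous-but-one state; accepted for interface completeness
#'   (persistence is defined on the current and previous year).
#' @param income_floor minimum income before the log transform (GBP/year).
#' @return list of logical flag vectors (`poverty_entry`, `poverty_exit`,
#'   `employment_entry`, `employment_exit`, `persistent_poverty`,
#'   `persistent_unemployment`), numeric `delta_log_income`, and `has_lag`.
#' @export
detect_transitions <- function(prev, cur, prev2 = NULL, income_floor = 1) {
  n <- length(cur$income)
  zero <- rep(FALSE, n)
  if (is.null(prev)) {
    return(list(poverty_entry = zero, poverty_exit = zero,
                employment_entry = zero, employment_exit = zero,
                persistent_poverty = zero, persistent_unemployment = zero,
                delta_log_income = numeric(n), has_lag = FALSE))
  }
  dli <- log(pmax(cur$income, income_floor)) - log(pmax(prev$income, income_floor))
  list(
    poverty_entry = !prev$in_poverty & cur$in_poverty,
    poverty_exit = prev$in_poverty & !cur$in_poverty,
    employment_entry = !prev$employed & cur$employed,
    employment_exit = prev$employed & !cur$employed,
    persistent_poverty = prev$in_poverty & cur$in_poverty,
    persistent_unemployment = !prev$employed & !cur$employed,
    delta_log_income = dli,
    has_lag = TRUE
  )
}

#' Step-2 adjusted CMD probability
#'
#' Adds the gender-specific risk differences of the active transition flags
#' and the log-income effect to the Step-1 baseline probability, clipping to
#' \[0, 1\].
#'
#' @param p0 baseline CMD probability (vectorised).
#' @param flags transition flags from [detect_transitions()].
#' @param effects an effect set from [load_effects()].
#' @param gender `"male"`/`"female"` (vectorised, recycled against `p0`).
#' @return adjusted probability vector.
#' @export
adjusted_cmd_probability <- function(p0, flags, effects, gender) {
  if (any(p0 < 0 | p0 > 1)) stop_domain("adjusted_cmd_probability: p0 outside [0,1]")
  if (!all(gender %in% c("male", "female"))) {
    stop_domain("configuration error: unknown gender key")
  }
  shift <- effect_shift(flags, effects, gender, scale = "rd")
  clip(p0 + shift, 0, 1)
}

# Shared shift computation for the binary ("rd") and Likert ("likert")
# scales; returns the additive effect per person.
effect_shift <- function(flags, effects, gender, scale = c("rd", "likert")) {
  scale <- match.arg(scale)
  get <- function(g, nm) {
    blk <- effects[[g]]
    if (scale == "likert") blk$likert[[nm]] else blk[[paste0("rd_", nm)]]
  }
  pick <- function(nm) {
    ifelse(gender == "male", get("male", nm), get("female", nm))
  }
  beta <- function(g) {
    if (scale == "likert") effects[[g]]$likert$beta_log_income
    else effects[[g]]$beta_log_income
  }
  pick("poverty_entry") * flags$poverty_entry +
    pick("poverty_exit") * flags$poverty_exit +
    pick("employment_entry") * flags$employment_entry +
    pick("employment_exit") * flags$employment_exit +
    pick("persistent_poverty") * flags$persistent_poverty +
    pick("persistent_unemployment") * flags$persistent_unemployment +
    ifelse(gender == "male", beta("male"), beta("female")) * flags$delta_log_income
}

#' Realise mental-health outcomes
#'
#' Binary CMD is a Bernoulli draw from the adjusted probability; the GHQ
#' Likert score is the person's baseline continuous score plus the parallel
#' continuous shift plus Gaussian noise, clipped to \[0, 36\]. The two
#' processes run in parallel (they share transition inputs but the binary
#' flag is not derived from the continuous score).
#'
#' @param p adjusted CMD probability (vectorised).
#' @param ghq_mu baseline continuous GHQ mean.
#' @param continuous_shift additive Likert-scale shift.
#' @param sigma Likert noise standard deviation.
#' @param seed integer seed.
#' @return list with logical `cmd` and numeric `ghq_likert`.
#' @export
realize_mental_health <- function(p, ghq_mu, continuous_shift = 0,
                                  sigma = 4.5, seed = 1L) {
  if (any(p < 0 | p > 1)) stop_domain("realize_mental_health: p outside [0,1]")
  set.seed(derive_seed(seed, 5L))
  n <- length(p)
  cmd <- stats::runif(n) < p
  ghq <- clip(ghq_mu + continuous_shift + stats::rnorm(n, 0, sigma), 0, 36)
  list(cmd = cmd, ghq_likert = ghq)
}
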