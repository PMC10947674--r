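# Annual simulation loop: wage/labour/tax resolution, poverty determination
# against baseline-anchored lines, mental-health update, state lagging.
# Counterfactual scenarios reuse the baseline replicate's poverty lines and
# per-year random streams (common random numbers).

#' Run one policy scenario over the simulation horizon
#'
#' Evolves the population in one-year increments: ages advance, wages are
#' re-evaluated on the aged deterministic profile (permanent residuals
#' fixed), benefit units choose joint hours by random-utility maximisation,
#' disposable incomes are computed by the tax-benefit calculator, poverty is
#' assessed against the (baseline-anchored) line, economic transitions feed
#' the Step-2 mental-health update, and lagged states shift. UBI is active
#' only from its schedule's start year, so intervention scenarios are
#' identical to baseline in pre-intervention years.
#'
#' Per-year random streams are derived from `(seed, year)` with fixed draw
#' order and sizes, so two scenarios run with the same seed share taste
#' shocks and outcome draws (common random numbers).
#'
#' @param population a `ubi_population` (with or without baseline mental
#'   health assigned; it is assigned internally in the first year).
#' @param scenario a `ubi_scenario`.
#' @param years contiguous simulation years (default 2022:2026).
#' @param params a `ubi_params` parameter set.
#' @param seed integer seed for the run's random streams.
#' @param poverty_lines named per-year poverty lines from the baseline run;
#'   `NULL` (allowed for the baseline scenario only) computes each year's
#'   line from the scenario's own incomes.
#' @param sens1_targets optional named per-year employment-rate targets; when
#'   supplied, the work-option utility offset is recalibrated each
#'   intervention year so the expected employment rate matches the target
#'   (fixed-employment sensitivity mode).
#' @param burn_in number of unrecorded warm-up years before the first
#'   recorded year (pre-reform policy), so recorded employment dynamics
#'   start near the stationary state of the choice process and the first
#'   recorded year has proper lagged states.
#' @param pre_reform policy applied before the scenario's UBI start year
#'   (and during burn-in); defaults to the shipped baseline scenario, so
#'   intervention scenarios are byte-identical to baseline pre-reform.
#' @return person-year panel (`data.frame`) for in-scope adults with
#'   attributes `poverty_lines`, `fiscal` (per-year aggregates) and
#'   `offsets` (calibrated offsets per year, if any).
#' @export
run_scenario <- function(population, scenario, years = 2022:2026, params,
                         seed = 1L, poverty_lines = NULL,
                         sens1_targets = NULL, burn_in = 2L,
                         pre_reform = NULL) {
  if (nrow(population$persons) == 0) {
    out <- empty_panel()
    attr(out, "poverty_lines") <- stats::setNames(numeric(0), character(0))
    attr(out, "fiscal") <- data.frame(year = integer(), taxes = numeric(),
                                      ubi = numeric(), benefits = numeric())
    return(out)
  }
  if (is.null(poverty_lines) && scenario$name != "baseline") {
    stop_domain("contract error: poverty lines must be supplied for counterfactual scenarios")
  }
  reform_year <- if (is.null(scenario$ubi)) -Inf else scenario$ubi$start_year
  if (is.null(pre_reform)) {
    pre_reform <- if (is.finite(reform_year)) load_scenario("baseline") else scenario
  }
  st <- build_labour_state(population)
  adults <- st$adults
  n_ad <- nrow(adults)
  n_units <- nrow(st$units)
  couple <- st$is_couple
  hours_set <- population$config$hours_set
  nH <- length(hours_set)
  prefs <- params$preferences
  effects <- params$effects
  income_floor <- 1  # GBP/year floor before log income change

  # Step-1 baseline mental health (deterministic predictors).
  has_children_ad <- st$has_children[match(adults$unit_id, st$units$unit_id)]
  p0 <- stats::plogis(mh_linear_predictor(adults, has_children_ad, params$mh_binary))
  ghq_mu <- mh_linear_predictor(adults, has_children_ad, params$mh_likert)

  # unit lookup per adult
  unit_row <- match(adults$unit_id, st$units$unit_id)
  base_age <- adults$age
  kid_base_age <- st$kid_age0
  kid_urow <- match(st$kid_unit, st$units$unit_id)

  eq_scale <- switch(population$config$equivalence_scale %||% "oecd",
                     oecd = 1 + 0.5 * (st$units$n_adults - 1) +
                       0.3 * st$units$n_children,
                     percapita = st$unit_size,
                     stop_domain("configuration error: unknown equivalence scale"))

  prev <- NULL      # list(employed, in_poverty, income) per adult
  prev_emp1 <- NULL; prev_emp2 <- NULL
  lines <- stats::setNames(rep(NA_real_, length(years)), years)
  fiscal <- data.frame(year = years, taxes = NA_real_, ubi = NA_real_,
                       benefits = NA_real_)
  offsets <- stats::setNames(rep(0, length(years)), years)
  panel <- vector("list", length(years))
  sim_years <- (years[1] - burn_in):years[length(years)]

  for (year in sim_years) {
    record <- year >= years[1]
    ti <- match(year, years)
    dy <- year - years[1]
    active <- if (year >= reform_year) scenario else pre_reform
    age <- base_age + dy
    kid_age <- kid_base_age + dy
    in_scope <- age >= 25 & age <= 64
    age1 <- age[st$a1]
    age2 <- ifelse(couple, age[st$a2], NA_real_)

    # wages on the aged profile, permanent residuals
    wage <- exp(wage_index(age, adults$gender, adults$education, params$wage) +
                  adults$wage_resid)
    wage1 <- wage[st$a1]
    wage2 <- ifelse(couple, wage[st$a2], NA_real_)

    # annual UBI for the unit's children (children aging past 15 move to
    # the adult rate automatically)
    still_child <- kid_age <= 18   # dependent children remain in the unit
    child_ubi <- group_sum(ubi_annual(kid_age, active$ubi, year) * still_child,
                           kid_urow, n_units)

    # ---- per-year random streams (keyed by calendar year, common across
    # scenarios) ---------------------------------------------------------
    set.seed(derive_seed(seed, 1000L + year))
    shocks <- matrix(rgumbel(n_units * nH * nH), n_units, nH * nH)
    u_cmd <- stats::runif(n_ad)
    eps_ghq <- stats::rnorm(n_ad, 0, params$mh_likert$sigma)

    # ---- labour supply --------------------------------------------------
    util_at <- function(offset) {
      option_utilities(st, wage1, wage2, age1, age2, child_ubi, active,
                       year, prefs, prev_emp1, prev_emp2, hours_set,
                       offset = offset)
    }
    base_offset <- prefs$employment_offset %||% 0
    offset <- base_offset
    if (!is.null(sens1_targets) && as.character(year) %in% names(sens1_targets) &&
        !is.null(scenario$ubi) && year >= scenario$ubi$start_year) {
      target <- sens1_targets[[as.character(year)]]
      in1 <- in_scope[st$a1]
      in2 <- ifelse(couple, in_scope[st$a2], FALSE)
      rate_fn <- function(o) {
        ou <- util_at(o)
        P <- logit_probs(ou$U, prefs$noise_scale)
        expected_employment_from_probs(st, P, ou$opts1, ou$opts2, in1, in2)
      }
      offset <- calibrate_employment_offset(rate_fn, target)
      if (record) offsets[ti] <- offset
    }
    ou <- util_at(offset)
    V <- ou$U / prefs$noise_scale + shocks
    V[!is.finite(ou$U)] <- -Inf
    choice <- max.col(V, ties.method = "first")
    h1 <- hours_set[((choice - 1L) %% nH) + 1L]
    h2 <- ifelse(couple, hours_set[((choice - 1L) %/% nH) + 1L], NA_real_)

    hours <- numeric(n_ad)
    hours[st$a1] <- h1
    hours[st$a2[couple]] <- h2[couple]
    employed <- hours > 0

    # ---- incomes, poverty ----------------------------------------------
    g1 <- wage1 * h1 * 52
    g2 <- ifelse(couple, wage2 * h2 * 52, NA_real_)
    res <- unit_disposable(g1, g2, age1, age2, st$units$n_children, child_ubi,
                           st$units$needs_support, active, year)
    disp_u <- res$disposable
    if (record) {
      fiscal$taxes[ti] <- sum(res$tax)
      fiscal$ubi[ti] <- sum(res$ubi)
      fiscal$benefits[ti] <- sum(res$benefits)
    }

    pc_income <- disp_u / eq_scale              # equivalised unit income
    adult_income <- disp_u / st$units$n_adults  # per adult
    pc_ad <- pc_income[unit_row]
    # pre-reform/burn-in years of a counterfactual are policy-identical to
    # baseline under common random numbers, so their lines are computed on
    # the fly; reform years use the supplied baseline-anchored lines.
    line <- if (!is.null(poverty_lines) && as.character(year) %in% names(poverty_lines) &&
                year >= reform_year) {
      poverty_lines[[as.character(year)]]
    } else if (!is.null(poverty_lines) && record && year >= reform_year) {
      stop_domain("contract error: missing poverty line for year ", year)
    } else {
      0.6 * stats::median(pc_ad[in_scope])
    }
    if (record) lines[ti] <- line
    in_pov <- pc_ad < line

    # ---- mental health --------------------------------------------------
    cur <- list(in_poverty = in_pov, employed = employed, income = pc_ad)
    flags <- detect_transitions(prev, cur, income_floor = income_floor)
    p <- adjusted_cmd_probability(p0, flags, effects, adults$gender)
    shift_l <- effect_shift(flags, effects, adults$gender, scale = "likert")
    cmd <- u_cmd < p
    ghq <- clip(ghq_mu + shift_l + eps_ghq, 0, 36)

    gross_ad <- numeric(n_ad)
    gross_ad[st$a1] <- g1
    gross_ad[st$a2[couple]] <- g2[couple]

    if (record) panel[[ti]] <- data.frame(
      scenario = scenario$name, year = year,
      person_id = adults$person_id, unit_id = adults$unit_id,
      age = age, gender = adults$gender, education = adults$education,
      in_scope = in_scope,
      has_children = has_children_ad,
      lone_parent = st$units$is_lone_parent[unit_row],
      hours = hours, employed = employed,
      gross_income = gross_ad,
      disposable_income = adult_income[unit_row],
      pc_income = pc_ad, in_poverty = in_pov,
      cmd_probability = p, cmd = cmd, ghq_likert = ghq,
      poverty_entry = flags$poverty_entry,
      poverty_exit = flags$poverty_exit,
      employment_entry = flags$employment_entry,
      employment_exit = flags$employment_exit,
      stringsAsFactors = FALSE
    )

    prev_emp1 <- h1 > 0
    prev_emp2 <- ifelse(couple, h2 > 0, NA)
    prev <- cur
  }
  out <- do.call(rbind, panel)
  attr(out, "poverty_lines") <- lines
  attr(out, "fiscal") <- fiscal
  attr(out, "offsets") <- offsets
  out
}

empty_panel <- function() {
  data.frame(scenario = character(), year = integer(), person_id = integer(),
             unit_id = integer(), age = integer(), gender = character(),
             education = character(), in_scope = logical(),
             has_children = logical(), lone_parent = logical(),
             hours = numeric(), employed = logical(), gross_income = numeric(),
             disposable_income = numeric(), pc_income = numeric(),
             in_poverty = logical(), cmd_probability = numeric(),
             cmd = logical(), ghq_likert = numeric(),
             poverty_entry = logical(), poverty_exit = logical(),
             employment_entry = logical(), employment_exit = logical(),
             stringsAsFactors = FALSE)
}

#' Poverty lines from a baseline panel
#'
#' Per year, 60% of the median per-capita benefit-unit disposable income
#' across in-scope adults (25-64), the income measure used for poverty.
#'
#' @param baseline_panel a panel from [run_scenario()].
#' @return named numeric vector of GBP/year lines by year.
#' @export
compute_poverty_lines <- function(baseline_panel) {
  years <- sort(unique(baseline_panel$year))
  if (length(years) == 0) stop_domain("compute_poverty_lines: empty panel")
  out <- vapply(years, function(y) {
    x <- baseline_panel$pc_income[baseline_panel$year == y & baseline_panel$in_scope]
    if (length(x) == 0) stop_domain("compute_poverty_lines: no in-scope adults in ", y)
    0.6 * stats::median(x)
  }, numeric(1))
  stats::setNames(out, years)
}

#' Run all configured scenarios for one replicate
#'
#' Generates the population and parameter set for the replicate, runs the
#' baseline scenario first, derives the poverty lines, then runs every
#' counterfactual with the same random streams (common random numbers) and
#' the baseline-anchored lines. Sensitivity modes: `sens1_fixed_employment`
#' recalibrates the work-option utility offset each intervention year so
#' Full/Full+ employment matches the baseline year's rate;
#' `sens2_inactivity` / `sens3_sysrev` substitute the Step-2 effect set.
#'
#' @param config a `ubi_run_config` from [parse_config()], or a generator
#'   config (then the remaining arguments apply).
#' @param replicate_seed integer seed for this replicate.
#' @param scenarios scenario names to run.
#' @param mode analysis mode (see [parse_config()]).
#' @param years simulation years.
#' @param draw_parameters draw the parameter set stochastically (`TRUE`) or
#'   use point estimates (`FALSE`).
#' @return named list of panels, with attribute `poverty_lines`.
#' @export
run_all <- function(config, replicate_seed = 1L,
                    scenarios = c("baseline", "partial", "full", "full_plus"),
                    mode = "primary", years = 2022:2026,
                    draw_parameters = TRUE) {
  if (inherits(config, "ubi_run_config")) {
    scenarios <- config$scenarios
    mode <- config$mode
    years <- config$years
    gen <- config$generator
  } else {
    gen <- config
  }
  if (!"baseline" %in% scenarios) scenarios <- c("baseline", scenarios)
  variant <- switch(mode, sens2_inactivity = "inactivity",
                    sens3_sysrev = "systematic_review", "primary")
  params <- if (draw_parameters) {
    draw_parameter_set(gen, derive_seed(replicate_seed, 101L), variant)
  } else {
    point_parameter_set(gen, variant)
  }
  pop <- generate_population(gen, derive_seed(replicate_seed, 102L))
  run_seed <- derive_seed(replicate_seed, 103L)
  panels <- run_all_panels(pop, params, scenarios, mode, years, run_seed)
  attr(panels, "poverty_lines") <- attr(panels$baseline, "poverty_lines")
  attr(panels, "params") <- params
  panels
}

#' Expected employment rate under a scenario
#'
#' Probability-weighted employment rate of in-scope adults from the
#' closed-form logit choice probabilities at baseline ages (no taste-shock
#' realisation), optionally with an employment offset; used by calibration
#' and its tests.
#'
#' @param population a `ubi_population`.
#' @param scenario a `ubi_scenario`.
#' @param params a `ubi_params`.
#' @param year calendar year.
#' @param offset work-option utility offset.
#' @param prev_employed optional logical vector (per adult, in unit order)
#'   of previous employment status for the inertia term.
#' @return expected employment rate (proportion).
#' @export
expected_employment <- function(population, scenario, params, year = 2023,
                                offset = 0, prev_employed = NULL) {
  st <- build_labour_state(population)
  couple <- st$is_couple
  age <- st$adults$age
  wage <- exp(wage_index(age, st$adults$gender, st$adults$education,
                         params$wage) + st$adults$wage_resid)
  n_units <- nrow(st$units)
  kid_urow <- match(st$kid_unit, st$units$unit_id)
  child_ubi <- group_sum(ubi_annual(st$kid_age0, scenario$ubi, year),
                         kid_urow, n_units)
  pe1 <- pe2 <- NULL
  if (!is.null(prev_employed)) {
    pe1 <- prev_employed[st$a1]
    pe2 <- ifelse(couple, prev_employed[st$a2], NA)
  }
  ou <- option_utilities(st, wage[st$a1],
                         ifelse(couple, wage[st$a2], NA_real_),
                         age[st$a1], ifelse(couple, age[st$a2], NA_real_),
                         child_ubi, scenario, year, params$preferences,
                         pe1, pe2, population$config$hours_set, offset = offset)
  P <- logit_probs(ou$U, params$preferences$noise_scale)
  in1 <- age[st$a1] >= 25 & age[st$a1] <= 64
  in2 <- ifelse(couple, age[st$a2] >= 25 & age[st$a2] <= 64, FALSE)
  expected_employment_from_probs(st, P, ou$opts1, ou$opts2, in1, in2)
}
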