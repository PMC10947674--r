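# Configuration: generator defaults, policy scenario and effect-set loaders,
# and run-configuration parsing. All tunable distributions live here so the
# whole pipeline is testable without any external data download.

#' Default synthetic-population generator configuration
#'
#' The shipped defaults define the study conditions: a UK-like working-age
#' population of benefit units (singles/couples, with/without children, lone
#' parents), three-level education, a log-linear hourly-wage model with
#' education/gender/age gradients, logistic baseline common-mental-disorder
#' (CMD) risk with an education gradient, and random-utility labour-supply
#' preferences. Defaults are calibrated so the baseline scenario reproduces
#' employment near 78.9%, poverty near 9.1% and a CMD relative index of
#' inequality near 1.33.
#'
#' @param n_persons target number of adults (default 25,000).
#' @return nested list of class `ubi_config`.
#' @export
default_generator_config <- function(n_persons = 25000L) {
  cfg <- list(
    n_persons = as.integer(n_persons),
    education_shares = c(low = 0.25, medium = 0.40, high = 0.35),
    couple_share = 0.64,          # share of adults living in couples
    child_presence_share = 0.55,  # share of couple units with children
    lone_parent_share = 0.22,     # share of single units with children
    lone_parent_female_share = 0.86,
    n_children_probs = c(`1` = 0.45, `2` = 0.40, `3` = 0.15),
    needs_support_share = 0.55,   # units flagged for means-tested categories
    equivalence_scale = "oecd",   # OECD-modified scale for the poverty measure
    hours_set = c(0, 10, 20, 30, 40),
    wage_coefficients = list(
      intercept = 2.35,           # log GBP/hour at reference (low educ, female, 45)
      medium = 0.22, high = 0.52, # education gradient on log wage
      male = 0.12,
      age = 0.004,                # per year of age, centred at 45
      sigma = 0.42,               # log-normal residual scale
      heckman_delta = 0.0         # optional inverse-Mills selection term, off
    ),
    preferences = list(
      income_weight = 0.70,       # utility per unit log disposable income
      leisure_weight = 0.004,     # utility per weekly hour of forgone leisure
      work_attachment = -0.24,    # fixed utility of being in work (net of costs)
      mother_penalty = -1.20,     # childcare adjustment, women in units w/ children
      inertia = 0.60,             # bonus for keeping last year's employment status
      noise_scale = 1.0,          # Gumbel taste-shock scale
      employment_offset = 0.0,    # additive utility on working options (sens. 1)
      income_floor = 100          # GBP/year floor inside log utility
    ),
    baseline_mh_coefficients = list(
      binary = list(intercept = -1.583, female = 0.10, low = 0.285,
                    medium = 0.158, age45 = -0.02, children = 0.04),
      likert = list(intercept = 10.2, female = 0.9, low = 1.3, medium = 0.7,
                    age45 = -0.2, children = 0.3, sigma = 4.5)
    ),
    calibration_targets = list(employment_pct = 78.9, poverty_pct = 9.1,
                               cmd_prevalence_pct = 20, cmd_rii = 1.33),
    parameter_covariances = default_parameter_sds()
  )
  class(cfg) <- c("ubi_config", "list")
  validate_generator_config(cfg)
  cfg
}

# Standard deviations for the (diagonal) parameter-uncertainty blocks; a full
# covariance matrix may be supplied instead of a vector for any block.
default_parameter_sds <- function() {
  list(
    wage = c(intercept = 0.02, medium = 0.02, high = 0.02, male = 0.015,
             age = 0.001),
    mh_binary = c(intercept = 0.05, female = 0.03, low = 0.05, medium = 0.04,
                  age45 = 0.03, children = 0.03),
    preferences = c(income_weight = 0.015, leisure_weight = 0.0004,
                    work_attachment = 0.03),
    effects_male = c(rd_poverty_entry = 0.0035, rd_poverty_exit = 0.0035,
                     rd_employment_exit = 0.02, rd_employment_entry = 0.02,
                     rd_persistent_poverty = 0.0035,
                     rd_persistent_unemployment = 0.012,
                     beta_log_income = 0.004),
    effects_female = c(rd_poverty_entry = 0.0025, rd_poverty_exit = 0.0025,
                       rd_employment_exit = 0.015, rd_employment_entry = 0.015,
                       rd_persistent_poverty = 0.0025,
                       rd_persistent_unemployment = 0.009,
                       beta_log_income = 0.004)
  )
}

#' Validate a generator configuration
#'
#' @param cfg configuration list as from [default_generator_config()].
#' @return the configuration, invisibly; errors on violations.
#' @export
validate_generator_config <- function(cfg) {
  if (cfg$n_persons < 0) stop_domain("configuration error: n_persons < 0")
  es <- cfg$education_shares
  if (abs(sum(es) - 1) > 1e-9) {
    stop_domain("configuration error: education_shares must sum to 1")
  }
  props <- c(es, cfg$couple_share, cfg$child_presence_share,
             cfg$lone_parent_share, cfg$lone_parent_female_share,
             cfg$needs_support_share)
  if (any(props < 0 | props > 1)) {
    stop_domain("configuration error: proportions must lie in [0,1]")
  }
  if (abs(sum(cfg$n_children_probs) - 1) > 1e-9) {
    stop_domain("configuration error: n_children_probs must sum to 1")
  }
  hs <- cfg$hours_set
  if (!0 %in% hs || is.unsorted(hs, strictly = TRUE)) {
    stop_domain("configuration error: hours_set must contain 0 and be strictly increasing")
  }
  if (cfg$preferences$noise_scale <= 0 || cfg$preferences$income_weight <= 0) {
    stop_domain("configuration error: noise_scale and income_weight must be positive")
  }
  for (nm in names(cfg$parameter_covariances)) {
    blk <- cfg$parameter_covariances[[nm]]
    if (is.matrix(blk)) {
      if (!isSymmetric(unname(blk), tol = 1e-8)) {
        stop_domain("configuration error: covariance block '", nm, "' not symmetric")
      }
      ev <- eigen(blk, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8 * max(abs(ev), 1)) {
        stop_domain("configuration error: covariance block '", nm,
                    "' not positive semi-definite")
      }
    } else if (any(blk < 0)) {
      stop_domain("configuration error: negative standard deviation in block '", nm, "'")
    }
  }
  invisible(cfg)
}

scenario_names <- c("baseline", "partial", "full", "full_plus")

#' Load a policy scenario definition
#'
#' Scenarios bundle a marginal tax schedule, an optional UBI schedule, and
#' stylized benefit rules. The four shipped scenarios (`baseline`,
#' `partial`, `full`, `full_plus`) live as YAML files under
#' `inst/extdata/scenarios/`.
#'
#' @param name one of the shipped scenario names, or a path to a YAML file.
#' @return scenario list of class `ubi_scenario`.
#' @export
load_scenario <- function(name) {
  path <- if (file.exists(name)) name else {
    system.file("extdata", "scenarios", paste0(name, ".yaml"),
                package = "ubisim", mustWork = FALSE)
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop_domain("configuration error: unknown scenario '", name, "'")
  }
  sc <- yaml::read_yaml(path)
  sc$tax$thresholds <- as.numeric(unlist(sc$tax$thresholds))
  sc$tax$rates <- as.numeric(unlist(sc$tax$rates))
  validate_scenario(sc)
  class(sc) <- c("ubi_scenario", "list")
  sc
}

validate_scenario <- function(sc) {
  validate_tax_schedule(sc$tax)
  if (identical(sc$name, "baseline") && !is.null(sc$ubi)) {
    stop_domain("configuration error: baseline scenario must have no UBI")
  }
  if (!is.null(sc$ubi)) {
    amounts <- c(sc$ubi$weekly_child, sc$ubi$weekly_adult, sc$ubi$weekly_pensioner)
    if (any(amounts < 0)) stop_domain("configuration error: negative UBI amount")
    if (sc$name %in% c("full", "full_plus") &&
        abs(sc$tax$allowance - 52 * sc$ubi$weekly_adult) > 0.01) {
      stop_domain("configuration error: Full/Full+ allowance must equal annualised adult UBI")
    }
  }
  invisible(sc)
}

#' Load the four shipped policy scenarios
#'
#' @return named list of `ubi_scenario` objects.
#' @export
default_scenarios <- function() {
  out <- lapply(scenario_names, load_scenario)
  names(out) <- scenario_names
  out
}

#' Load a Step-2 effect-estimate set
#'
#' Gender-specific risk differences (and parallel continuous GHQ effects)
#' for economic transitions. Shipped variants: `primary`, `inactivity`
#' (employment exits treated as economic inactivity) and
#' `systematic_review` (magnitudes from review literature).
#'
#' @param variant variant name or path to a YAML file.
#' @return list of class `ubi_effects` with `male`/`female` sublists.
#' @export
load_effects <- function(variant = "primary") {
  path <- if (file.exists(variant)) variant else {
    system.file("extdata", "effects", paste0(variant, ".yaml"),
                package = "ubisim", mustWork = FALSE)
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop_domain("configuration error: unknown effect set '", variant, "'")
  }
  ef <- yaml::read_yaml(path)
  for (g in c("male", "female")) {
    rds <- unlist(ef[[g]][startsWith(names(ef[[g]]), "rd_")])
    if (any(abs(rds) >= 1)) {
      stop_domain("configuration error: risk differences must lie in (-1, 1)")
    }
  }
  class(ef) <- c("ubi_effects", "list")
  ef
}

run_modes <- c("primary", "sens1_fixed_employment", "sens2_inactivity",
               "sens3_sysrev")

#' Parse a run configuration file
#'
#' Reads a YAML run configuration (generator overrides, scenario list,
#' analysis mode, years, replicates, base seed, output directory), validates
#' it against the closed schema and returns a fully populated `RunConfig`.
#' Unknown keys are rejected by name.
#'
#' @param path path to a YAML file.
#' @return list of class `ubi_run_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop_domain("configuration error: no such file: ", path)
  raw <- yaml::read_yaml(path)
  allowed <- c("generator", "scenarios", "mode", "years", "n_reps",
               "base_seed", "output_dir")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    stop_domain("configuration error: unknown key(s) ",
                paste0("'", bad, "'", collapse = ", "))
  }
  gen <- merge_config(unclass(default_generator_config()), raw$generator,
                      path = "generator.")
  # YAML sequences arrive as lists; restore the numeric-vector fields.
  for (f in c("education_shares", "n_children_probs", "hours_set")) {
    gen[[f]] <- unlist(gen[[f]])
  }
  gen$parameter_covariances <- lapply(gen$parameter_covariances, function(b) {
    if (is.matrix(b)) b else unlist(b)
  })
  class(gen) <- c("ubi_config", "list")
  validate_generator_config(gen)
  scens <- raw$scenarios %||% scenario_names
  bad_sc <- setdiff(scens, scenario_names)
  if (length(bad_sc)) {
    stop_domain("configuration error: unknown scenario name(s) ",
                paste0("'", bad_sc, "'", collapse = ", "))
  }
  mode <- raw$mode %||% "primary"
  if (!mode %in% run_modes) {
    stop_domain("configuration error: unknown mode '", mode, "' (allowed: ",
                paste(run_modes, collapse = ", "), ")")
  }
  years <- raw$years %||% 2022:2026
  if (length(years) >= 2) years <- years[1]:years[length(years)]
  cfg <- list(generator = gen, scenarios = scens, mode = mode,
              years = as.integer(years),
              n_reps = as.integer(raw$n_reps %||% 1000L),
              base_seed = as.integer(raw$base_seed %||% 1L),
              output_dir = raw$output_dir %||% "results")
  class(cfg) <- c("ubi_run_config", "list")
  cfg
}

#' Write a run configuration to YAML
#'
#' Round-trips with [parse_config()]: writing then re-parsing yields the
#' same configuration.
#'
#' @param config a `ubi_run_config` (or compatible list).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- list(generator = unclass(config$generator),
              scenarios = config$scenarios,
              mode = config$mode,
              years = config$years,
              n_reps = config$n_reps,
              base_seed = config$base_seed,
              output_dir = config$output_dir)
  yaml::write_yaml(out, path)
  invisible(path)
}
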