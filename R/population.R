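# Synthetic population generator: benefit units of working-age adults
# (25-64) with children, education, wage potential and baseline mental
# health, plus stochastic parameter draws for uncertainty replicates.

#' Generate a synthetic baseline population
#'
#' Builds benefit units (singles and couples, with and without children,
#' including lone parents) and their members. Adults span ages 25-64
#' uniformly; children 0-15 uniformly. Education, partnership and children
#' are assigned from the configured shares; hourly wage potential is drawn
#' from the log-linear wage model. Deterministic given `(config, seed)`.
#'
#' @param config generator configuration, see [default_generator_config()].
#' @param seed integer seed.
#' @return list of class `ubi_population` with data frames `persons` and
#'   `units`.
#' @export
generate_population <- function(config = default_generator_config(), seed = 1L) {
  validate_generator_config(config)
  n <- config$n_persons
  empty <- function() {
    structure(list(
      persons = data.frame(person_id = integer(), unit_id = integer(),
                           household_id = integer(), age = integer(),
                           gender = character(), education = character(),
                           is_adult = logical(), wage_resid = numeric(),
                           wage_potential = numeric()),
      units = data.frame(unit_id = integer(), n_adults = integer(),
                         n_children = integer(), is_lone_parent = logical(),
                         needs_support = logical()),
      config = config, seed = as.integer(seed)),
      class = c("ubi_population", "list"))
  }
  if (n == 0) return(empty())
  set.seed(derive_seed(seed, 1L))

  # --- benefit-unit structure -------------------------------------------
  n_couple_units <- floor(n * config$couple_share / 2)
  n_single_units <- n - 2L * n_couple_units
  n_units <- n_couple_units + n_single_units
  unit_n_adults <- c(rep(2L, n_couple_units), rep(1L, n_single_units))
  has_children <- c(
    stats::runif(n_couple_units) < config$child_presence_share,
    stats::runif(n_single_units) < config$lone_parent_share
  )
  kid_counts <- as.integer(names(config$n_children_probs))
  n_children <- ifelse(has_children,
                       sample(kid_counts, n_units, replace = TRUE,
                              prob = config$n_children_probs), 0L)
  is_lone_parent <- unit_n_adults == 1L & n_children > 0L
  needs_support <- stats::runif(n_units) < config$needs_support_share

  # --- adults ------------------------------------------------------------
  unit_of_adult <- rep(seq_len(n_units), times = unit_n_adults)
  n_adults <- length(unit_of_adult)
  first_in_unit <- !duplicated(unit_of_adult)
  age <- integer(n_adults)
  age[first_in_unit] <- sample(25:64, n_units, replace = TRUE)
  partner <- which(!first_in_unit)
  age[partner] <- clip(age[partner - 1L] + round(stats::rnorm(length(partner), 0, 3)),
                       25L, 64L)
  gender <- character(n_adults)
  # couples are male/female pairs; singles 50/50 except lone parents,
  # who are predominantly female
  gender[first_in_unit & unit_of_adult %in% which(unit_n_adults == 2L)] <- "male"
  gender[partner] <- "female"
  single_rows <- which(first_in_unit & unit_of_adult %in% which(unit_n_adults == 1L))
  lone <- is_lone_parent[unit_of_adult[single_rows]]
  p_female <- ifelse(lone, config$lone_parent_female_share, 0.5)
  gender[single_rows] <- ifelse(stats::runif(length(single_rows)) < p_female,
                                "female", "male")
  education <- sample(c("low", "medium", "high"), n_adults, replace = TRUE,
                      prob = config$education_shares)

  # --- children ----------------------------------------------------------
  n_kids_total <- sum(n_children)
  kid_unit <- rep(seq_len(n_units), times = n_children)
  kid_age <- if (n_kids_total > 0) sample(0:15, n_kids_total, replace = TRUE) else integer()
  kid_gender <- if (n_kids_total > 0) {
    sample(c("male", "female"), n_kids_total, replace = TRUE)
  } else character()

  persons <- data.frame(
    person_id = seq_len(n_adults + n_kids_total),
    unit_id = c(unit_of_adult, kid_unit),
    household_id = c(unit_of_adult, kid_unit),  # one benefit unit per household
    age = c(age, kid_age),
    gender = c(gender, kid_gender),
    education = c(education, rep(NA_character_, n_kids_total)),
    is_adult = c(rep(TRUE, n_adults), rep(FALSE, n_kids_total)),
    stringsAsFactors = FALSE
  )
  wage_resid <- stats::rnorm(n_adults, 0, config$wage_coefficients$sigma)
  persons$wage_resid <- c(wage_resid, rep(NA_real_, n_kids_total))
  persons$wage_potential <- NA_real_
  persons$wage_potential[seq_len(n_adults)] <-
    exp(wage_index(age, gender, education, config$wage_coefficients) + wage_resid)

  units <- data.frame(unit_id = seq_len(n_units), n_adults = unit_n_adults,
                      n_children = n_children, is_lone_parent = is_lone_parent,
                      needs_support = needs_support)
  structure(list(persons = persons, units = units, config = config,
                 seed = as.integer(seed)),
            class = c("ubi_population", "list"))
}

# Deterministic part of the log-wage equation, optionally with a
# Heckman-style inverse-Mills selection correction (off by default).
wage_index <- function(age, gender, education, wc) {
  idx <- wc$intercept +
    wc$medium * (education == "medium") +
    wc$high * (education == "high") +
    wc$male * (gender == "male") +
    wc$age * (age - 45)
  if ((wc$heckman_delta %||% 0) != 0) {
    z <- (idx - mean(idx)) / max(stats::sd(idx), 1e-9)
    idx <- idx + wc$heckman_delta * stats::dnorm(z) / stats::pnorm(z)
  }
  idx
}

#' Potential hourly wage
#'
#' Exponentiated linear index in education, gender and age, plus an optional
#' selection-correction term and log-normal noise. Deterministic for a fixed
#' seed; always positive.
#'
#' @param persons data frame with `age`, `gender`, `education` columns.
#' @param params parameter set (uses its `wage` block), see
#'   [draw_parameter_set()].
#' @param seed integer seed for the noise draw.
#' @return GBP/hour, one value per row of `persons`.
#' @export
potential_wage <- function(persons, params, seed = 1L) {
  set.seed(derive_seed(seed, 7L))
  wc <- params$wage
  noise <- stats::rnorm(nrow(persons), 0, wc$sigma)
  exp(wage_index(persons$age, persons$gender, persons$education, wc) + noise)
}

#' Draw a coherent parameter set for one replicate
#'
#' Multivariate-normal draws around the configured point estimates for the
#' wage equation, Step-1 mental-health coefficients, labour-supply
#' preferences and Step-2 effect estimates, using the configured
#' variance-covariance blocks (diagonal standard deviations or full
#' matrices). Zero covariance returns the point estimates exactly.
#'
#' @param config generator configuration.
#' @param seed integer seed.
#' @param effects_variant which Step-2 effect set the draw is centred on.
#' @return list of class `ubi_params` with blocks `wage`, `mh_binary`,
#'   `mh_likert`, `preferences`, `effects`.
#' @export
draw_parameter_set <- function(config = default_generator_config(), seed = 1L,
                               effects_variant = "primary") {
  validate_generator_config(config)
  set.seed(derive_seed(seed, 2L))
  sds <- config$parameter_covariances
  draw_block <- function(point, block) {
    if (is.null(block)) return(point)
    mu <- unlist(point[names_of_block(block)])
    Sigma <- if (is.matrix(block)) block else diag(block^2, nrow = length(block))
    if (all(Sigma == 0)) return(point)
    drawn <- as.numeric(MASS::mvrnorm(1, mu = mu, Sigma = Sigma))
    point[names_of_block(block)] <- as.list(drawn)
    point
  }
  names_of_block <- function(block) {
    if (is.matrix(block)) colnames(block) else names(block)
  }
  effects <- load_effects(effects_variant)
  effects$male <- draw_block(effects$male, sds$effects_male)
  effects$female <- draw_block(effects$female, sds$effects_female)
  params <- list(
    wage = draw_block(config$wage_coefficients, sds$wage),
    mh_binary = draw_block(config$baseline_mh_coefficients$binary, sds$mh_binary),
    mh_likert = config$baseline_mh_coefficients$likert,
    preferences = draw_block(config$preferences, sds$preferences),
    effects = effects
  )
  class(params) <- c("ubi_params", "list")
  params
}

#' Point-estimate parameter set
#'
#' The undrawn parameter set (all covariances treated as zero); used for
#' single deterministic runs.
#'
#' @inheritParams draw_parameter_set
#' @return `ubi_params` list.
#' @export
point_parameter_set <- function(config = default_generator_config(),
                                effects_variant = "primary") {
  params <- list(
    wage = config$wage_coefficients,
    mh_binary = config$baseline_mh_coefficients$binary,
    mh_likert = config$baseline_mh_coefficients$likert,
    preferences = config$preferences,
    effects = load_effects(effects_variant)
  )
  class(params) <- c("ubi_params", "list")
  params
}

# Step-1 linear predictors for the binary (logit scale) and continuous
# (Likert scale) baseline mental-health models.
mh_linear_predictor <- function(persons, has_children, coefs) {
  coefs$intercept +
    coefs$female * (persons$gender == "female") +
    coefs$low * (persons$education == "low") +
    coefs$medium * (persons$education == "medium") +
    coefs$age45 * (persons$age >= 45) +
    coefs$children * has_children
}

#' Assign baseline mental health (Step 1)
#'
#' Each adult's probability of likely common mental disorder (CMD) comes
#' from the Step-1 logistic model in gender, education, age band and
#' presence of children; the binary `cmd` flag is a Bernoulli draw from that
#' probability and the continuous GHQ Likert score is drawn from the
#' parallel linear model, clipped to \[0, 36\].
#'
#' @param population a `ubi_population`.
#' @param params a `ubi_params` parameter set.
#' @param seed integer seed.
#' @return the population with `p_cmd`, `ghq_mu`, `cmd` and `ghq_likert`
#'   filled in for adults.
#' @export
assign_baseline_mental_health <- function(population, params, seed = 1L) {
  persons <- population$persons
  adults <- which(persons$is_adult)
  if (length(adults) == 0) {
    population$persons$p_cmd <- numeric(0)
    return(population)
  }
  kids_by_unit <- population$units$n_children[match(persons$unit_id[adults],
                                                    population$units$unit_id)]
  has_children <- kids_by_unit > 0
  ad <- persons[adults, ]
  p <- stats::plogis(mh_linear_predictor(ad, has_children, params$mh_binary))
  mu <- mh_linear_predictor(ad, has_children, params$mh_likert)
  set.seed(derive_seed(seed, 3L))
  cmd <- stats::runif(length(adults)) < p
  ghq <- clip(mu + stats::rnorm(length(adults), 0, params$mh_likert$sigma), 0, 36)
  persons$p_cmd <- persons$ghq_mu <- NA_real_
  persons$cmd <- NA
  persons$ghq_likert <- NA_real_
  persons$p_cmd[adults] <- p
  persons$ghq_mu[adults] <- mu
  persons$cmd[adults] <- cmd
  persons$ghq_likert[adults] <- ghq
  population$persons <- persons
  population
}
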