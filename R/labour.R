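# Discrete-hours labour supply by random-utility maximisation at the
# benefit-unit level. Systematic utility is
#   U = w_inc * log(disposable) - w_leis * hours (+ mother extra)
#       + inertia * 1(employment status kept) + offset * 1(hours > 0),
# summed over the unit's adults, plus independent Gumbel taste shocks per
# joint option, which yields multinomial-logit choice probabilities.

#' Enumerate joint hours options for a benefit unit
#'
#' Singles choose from the hours set; couples make one joint choice over
#' the Cartesian product (unitary model).
#'
#' @param n_adults 1 or 2.
#' @param hours_set ordered vector of weekly hours options (contains 0).
#' @return matrix with one row per joint option and one column per adult.
#' @export
enumerate_choices <- function(n_adults, hours_set = c(0, 10, 20, 30, 40)) {
  if (!n_adults %in% c(1L, 2L)) {
    stop_domain("enumerate_choices: a benefit unit has 1 or 2 adults")
  }
  if (n_adults == 1L) {
    matrix(hours_set, ncol = 1, dimnames = list(NULL, "h1"))
  } else {
    g <- expand.grid(h1 = hours_set, h2 = hours_set)
    as.matrix(g)
  }
}

# Internal engine state for vectorised choice over the whole population:
# a list describing singles and couples separately. Built once per run.
build_labour_state <- function(population) {
  persons <- population$persons
  units <- population$units
  adults <- persons[persons$is_adult, ]
  ord <- order(adults$unit_id, adults$person_id)
  adults <- adults[ord, ]
  first <- !duplicated(adults$unit_id)
  u <- units[match(unique(adults$unit_id), units$unit_id), ]
  a1 <- which(first)
  a2 <- rep(NA_integer_, nrow(u))
  a2[u$n_adults == 2L] <- a1[u$n_adults == 2L] + 1L
  kids <- persons[!persons$is_adult, ]
  list(adults = adults, units = u, a1 = a1, a2 = a2,
       is_couple = u$n_adults == 2L,
       kid_unit = kids$unit_id, kid_age0 = kids$age,
       unit_size = u$n_adults + u$n_children,
       has_children = (u$n_children > 0))
}

# Systematic utilities for every unit x option. Returns list with matrices
# `U` (n_units x n_options, singles padded with -Inf beyond their options),
# `disp` (unit disposable income per option) and bookkeeping vectors.
option_utilities <- function(st, wage1, wage2, age1, age2, child_ubi,
                             scenario, year, prefs,
                             prev_emp1 = NULL, prev_emp2 = NULL,
                             hours_set = c(0, 10, 20, 30, 40),
                             offset = NULL) {
  offset <- offset %||% prefs$employment_offset %||% 0
  nH <- length(hours_set)
  n_units <- length(wage1)
  couple <- st$is_couple
  opts1 <- rep(hours_set, times = nH)    # adult 1 hours by joint option
  opts2 <- rep(hours_set, each = nH)     # adult 2 hours by joint option
  n_opt <- nH * nH
  U <- matrix(-Inf, n_units, n_opt)
  D <- matrix(NA_real_, n_units, n_opt)
  gender2 <- rep(NA_character_, n_units)
  gender2[couple] <- st$adults$gender[st$a2[couple]]
  # fixed utility of being in work (attachment net of fixed costs such as
  # commuting; reduced for women in units with children by childcare)
  fc1 <- prefs$work_attachment +
    prefs$mother_penalty * (st$adults$gender[st$a1] == "female" & st$has_children)
  fc2 <- ifelse(couple,
                prefs$work_attachment +
                  prefs$mother_penalty * (gender2 == "female" & st$has_children),
                0)
  lw1 <- lw2 <- prefs$leisure_weight
  floor_ <- prefs$income_floor %||% 100
  for (k in seq_len(n_opt)) {
    h1 <- opts1[k]; h2 <- opts2[k]
    valid <- couple | (h2 == 0)      # singles only have h2 == 0 options
    if (!any(valid)) next
    g1 <- wage1 * h1 * 52
    g2 <- ifelse(couple, wage2 * h2 * 52, NA_real_)
    res <- unit_disposable(g1, g2, age1, age2, st$units$n_children,
                           child_ubi, st$units$needs_support, scenario, year)
    disp <- res$disposable
    u <- prefs$income_weight * log(pmax(disp, floor_)) -
      lw1 * h1 - lw2 * h2 * couple +
      fc1 * (h1 > 0) + fc2 * (h2 > 0) * couple +
      offset * ((h1 > 0) + couple * (h2 > 0))
    if (!is.null(prev_emp1)) {
      keep1 <- (h1 > 0) == prev_emp1
      keep2 <- ifelse(couple, (h2 > 0) == prev_emp2, 0)
      u <- u + prefs$inertia * (keep1 + keep2)
    }
    U[valid, k] <- u[valid]
    D[valid, k] <- disp[valid]
  }
  list(U = U, disp = D, opts1 = opts1, opts2 = opts2, n_opt = n_opt)
}

# Multinomial-logit probabilities from a utility matrix (rows = units);
# -Inf entries (unavailable options) get probability 0.
logit_probs <- function(U, noise_scale) {
  V <- U / noise_scale
  m <- apply(V, 1, max)
  E <- exp(V - m)
  E[!is.finite(E)] <- 0
  E / rowSums(E)
}

#' Closed-form choice probabilities for one benefit unit
#'
#' Multinomial-logit probabilities over a unit's joint hours options under a
#' policy scenario, from the systematic utilities (no taste shocks).
#'
#' @param unit list with `wages` (one per adult), `ages`, optional
#'   `n_children`, `child_ages`, `needs_support`, `prev_employed` (logical
#'   per adult).
#' @param scenario policy scenario.
#' @param prefs preference parameters (see
#'   [default_generator_config()]`$preferences`).
#' @param year calendar year.
#' @param hours_set weekly hours options.
#' @return data frame of joint options with utilities and probabilities.
#' @export
choice_probabilities <- function(unit, scenario, prefs, year = 2023,
                                 hours_set = c(0, 10, 20, 30, 40)) {
  n_adults <- length(unit$wages)
  opts <- enumerate_choices(n_adults, hours_set)
  n_children <- unit$n_children %||% 0L
  child_ages <- unit$child_ages %||% rep(8L, n_children)
  child_ubi <- if (n_children > 0) sum(ubi_annual(child_ages, scenario$ubi, year)) else 0
  floor_ <- prefs$income_floor %||% 100
  disp <- numeric(nrow(opts))
  for (i in seq_len(nrow(opts))) {
    gross <- unit$wages * opts[i, ] * 52
    disp[i] <- disposable_income(
      list(gross = gross, ages = unit$ages, n_children = n_children,
           child_ages = child_ages, needs_support = unit$needs_support %||% FALSE),
      scenario, year)
  }
  genders <- unit$genders %||% rep("female", n_adults)
  fc <- prefs$work_attachment +
    prefs$mother_penalty * (genders == "female" & n_children > 0)
  U <- prefs$income_weight * log(pmax(disp, floor_)) -
    prefs$leisure_weight * rowSums(opts) +
    as.numeric((opts > 0) %*% fc) +
    (prefs$employment_offset %||% 0) * rowSums(opts > 0)
  if (!is.null(unit$prev_employed)) {
    U <- U + prefs$inertia *
      rowSums(sweep(opts > 0, 2, unit$prev_employed, `==`))
  }
  if (any(!is.finite(U))) stop_domain("choice_probabilities: non-finite utility")
  p <- exp((U - max(U)) / prefs$noise_scale)
  p <- p / sum(p)
  cbind(as.data.frame(opts), data.frame(disposable = disp, utility = U,
                                        probability = p))
}

#' Realise an hours choice for one benefit unit
#'
#' Adds independent Gumbel taste shocks to the systematic utilities of every
#' joint option and returns the argmax.
#'
#' @inheritParams choice_probabilities
#' @param seed integer seed.
#' @return named numeric vector of chosen weekly hours, one per adult.
#' @export
choose_hours <- function(unit, scenario, prefs, year = 2023, seed = 1L,
                         hours_set = c(0, 10, 20, 30, 40)) {
  tab <- choice_probabilities(unit, scenario, prefs, year, hours_set)
  set.seed(derive_seed(seed, 11L))
  shocks <- prefs$noise_scale * rgumbel(nrow(tab))
  k <- which.max(tab$utility + shocks)
  hcols <- grep("^h[12]$", names(tab), value = TRUE)
  out <- as.numeric(tab[k, hcols])
  names(out) <- hcols
  out
}

# Population-level expected employment rate (probability-weighted share of
# in-scope adults with positive hours) given a utility matrix.
expected_employment_from_probs <- function(st, P, opts1, opts2, in_scope1, in_scope2) {
  p_work1 <- rowSums(P[, opts1 > 0, drop = FALSE])
  p_work2 <- rowSums(P[, opts2 > 0, drop = FALSE])
  num <- sum(p_work1[in_scope1]) + sum(p_work2[st$is_couple & in_scope2], na.rm = TRUE)
  den <- sum(in_scope1) + sum(st$is_couple & in_scope2, na.rm = TRUE)
  num / den
}

#' Calibrate the employment offset to a target employment rate
#'
#' Bisection on the additive work-option utility offset until the expected
#' aggregate employment rate (computed from the closed-form logit
#' probabilities, no simulation noise) is within `tolerance` of
#' `target_rate`. Used by the fixed-employment sensitivity mode to hold
#' scenario employment at the baseline rate.
#'
#' @param utility_fn function(offset) returning the expected employment rate.
#' @param target_rate target employment rate (proportion in \[0,1\]).
#' @param tolerance absolute tolerance on the rate (default 0.001 = 0.1 pp).
#' @param bounds initial offset bracket; expanded once if needed.
#' @return calibrated offset (scalar).
#' @export
calibrate_employment_offset <- function(utility_fn, target_rate,
                                        tolerance = 0.001,
                                        bounds = c(-10, 10)) {
  if (target_rate <= 0 || target_rate >= 1) {
    # logit choice probabilities can never reach the boundary exactly
    stop_domain("calibration failure: target employment rate not attainable")
  }
  f <- function(o) utility_fn(o) - target_rate
  lo <- bounds[1]; hi <- bounds[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0) {   # expected employment is nondecreasing in offset
    lo <- lo * 5; hi <- hi * 5
    flo <- f(lo); fhi <- f(hi)
    if (flo > 0 || fhi < 0) {
      stop_domain("calibration failure: target employment rate not attainable")
    }
  }
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tolerance) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  stop_domain("calibration failure: bisection did not converge")
}
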