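# Static tax-benefit calculator: marginal income tax, UBI payments, stylized
# benefit categories, benefit-unit disposable income, and distributional
# summaries (Gini, fiscal balance).

#' Marginal income tax
#'
#' Tax due under a bracketed marginal schedule. The schedule is a list with
#' `allowance` (tax-free amount, GBP/year) and ascending `thresholds` with
#' matching marginal `rates`; income between `thresholds[i]` and
#' `thresholds[i+1]` is taxed at `rates[i]`, income above the last threshold
#' at the last rate. The first threshold is normally the allowance itself.
#' Continuous and nondecreasing in income, zero at or below the allowance.
#'
#' @param income total taxable income, GBP/year (vectorised, must be >= 0).
#' @param schedule list with `allowance`, `thresholds`, `rates`.
#' @return tax due, GBP/year.
#' @export
income_tax <- function(income, schedule) {
  validate_tax_schedule(schedule)
  if (any(income < 0)) stop_domain("income_tax: negative income")
  th <- schedule$thresholds
  ra <- schedule$rates
  upper <- c(th[-1], Inf)
  tax <- numeric(length(income))
  for (i in seq_along(th)) {
    tax <- tax + ra[i] * pmax(0, pmin(income, upper[i]) - th[i])
  }
  tax
}

validate_tax_schedule <- function(schedule) {
  th <- schedule$thresholds
  ra <- schedule$rates
  if (is.null(th) || is.null(ra) || length(th) != length(ra)) {
    stop_domain("tax schedule: thresholds and rates must have equal length")
  }
  if (is.unsorted(th, strictly = TRUE)) {
    stop_domain("tax schedule: thresholds must be strictly increasing")
  }
  if (any(ra < 0 | ra > 1)) stop_domain("tax schedule: rates must be in [0,1]")
  if (!is.null(schedule$allowance) && th[1] < schedule$allowance - 1e-9) {
    stop_domain("tax schedule: first threshold below allowance")
  }
  invisible(TRUE)
}

#' Weekly UBI payment by age
#'
#' Child rate for ages 0-15, adult rate from 16, pensioner rate from the
#' configured pension age (default 66). Zero before the schedule's start
#' year or when `ubi` is `NULL` (baseline).
#'
#' @param age age in years (vectorised).
#' @param ubi UBI schedule: list with `weekly_child`, `weekly_adult`,
#'   `weekly_pensioner`, `start_year`, optional `pension_age` (default 66);
#'   or `NULL` for no UBI.
#' @param year calendar year of payment.
#' @return GBP/week.
#' @export
ubi_payment <- function(age, ubi, year) {
  if (is.null(ubi) || year < ubi$start_year) return(numeric(length(age)) * 0)
  pension_age <- ubi$pension_age %||% 66
  out <- rep(ubi$weekly_adult, length(age))
  out[age <= 15] <- ubi$weekly_child
  out[age >= pension_age] <- ubi$weekly_pensioner
  out
}

# Annualised UBI (52 weeks/year throughout the package).
ubi_annual <- function(age, ubi, year) 52 * ubi_payment(age, ubi, year)

# Stylized benefit categories, all configurable per scenario. Each retained
# category pays a flat annual amount to eligible units; a suspended category
# contributes exactly 0. `earnings` is the unit's earned (pre-UBI) gross
# income; eligibility is a simple income cutoff per category.
benefit_amounts <- function(rules, earnings, n_adults, n_children, needs_support) {
  zero <- numeric(length(earnings))
  amt <- function(cat, value) if (isTRUE(rules[[cat]]$retained)) value else zero
  cb <- amt("child_benefit",
            rules$child_benefit$per_child * n_children *
              (earnings < rules$child_benefit$earnings_cutoff))
  ub <- amt("unemployment_benefit",
            (rules$unemployment_benefit$single +
               rules$unemployment_benefit$couple_supplement * (n_adults == 2) +
               (rules$unemployment_benefit$per_child %||% 0) * n_children) *
              (earnings <= 0))
  is_ <- amt("income_support",
             (rules$income_support$amount +
                (rules$income_support$per_child %||% 0) * n_children) *
               (earnings > 0 & earnings < rules$income_support$earnings_cutoff))
  mt <- amt("means_tested",
            rules$means_tested$amount * needs_support *
              (earnings < rules$means_tested$earnings_cutoff))
  ms <- amt("maternity_sick_student", rules$maternity_sick_student$amount + zero)
  total <- cb + ub + is_ + mt + ms
  if (!is.null(rules$benefit_cap)) total <- pmin(total, rules$benefit_cap)
  total
}

# Vectorised core of the tax-benefit calculator. All arguments are unit-level
# vectors; gross2/age2 are NA for single-adult units. Returns a list of
# unit-level components (GBP/year).
unit_disposable <- function(gross1, gross2, age1, age2, n_children,
                            child_ubi, needs_support, scenario, year) {
  couple <- !is.na(gross2)
  u1 <- ubi_annual(age1, scenario$ubi, year)
  t1 <- income_tax(gross1 + u1, scenario$tax)
  net <- gross1 + u1 - t1
  tax <- t1
  ubi <- u1
  if (any(couple)) {
    g2 <- ifelse(couple, gross2, 0)
    a2 <- ifelse(couple, age2, 40)
    u2 <- ubi_annual(a2, scenario$ubi, year) * couple
    t2 <- income_tax(g2 + u2, scenario$tax) * couple
    net <- net + g2 + u2 - t2
    tax <- tax + t2
    ubi <- ubi + u2
  }
  earnings <- gross1 + ifelse(couple, gross2, 0)
  ben <- benefit_amounts(scenario$benefits, earnings,
                         n_adults = 1L + couple, n_children = n_children,
                         needs_support = needs_support)
  list(disposable = net + child_ubi + ben,
       tax = tax, ubi = ubi + child_ubi, benefits = ben)
}

#' Disposable income of a benefit unit
#'
#' Converts a benefit unit's gross member incomes to annual disposable
#' income under a policy scenario: each member's gross income plus any UBI
#' (taxable) minus income tax, plus the unit's UBI for children and retained
#' stylized benefits (capped where a benefit cap applies). Never less than
#' the unit's total UBI.
#'
#' @param unit list with `gross` (numeric vector, one per adult), `ages`
#'   (adult ages), `n_children` (default 0), `child_ages` (defaults to age 8
#'   for each child), `needs_support` (logical, default `FALSE`).
#' @param scenario a policy scenario, see [default_scenarios()].
#' @param year calendar year.
#' @return disposable income, GBP/year (scalar).
#' @export
disposable_income <- function(unit, scenario, year) {
  gross <- unit$gross
  ages <- unit$ages
  if (is.null(gross) || is.null(ages) || length(gross) != length(ages)) {
    stop_domain("disposable_income: unresolved members (gross/ages mismatch)")
  }
  if (length(gross) < 1L || length(gross) > 2L) {
    stop_domain("disposable_income: a benefit unit has 1 or 2 adults")
  }
  n_children <- unit$n_children %||% 0L
  child_ages <- unit$child_ages %||% rep(8L, n_children)
  child_ubi <- if (n_children > 0) {
    sum(ubi_annual(child_ages, scenario$ubi, year))
  } else 0
  res <- unit_disposable(
    gross1 = gross[1],
    gross2 = if (length(gross) == 2L) gross[2] else NA_real_,
    age1 = ages[1],
    age2 = if (length(ages) == 2L) ages[2] else NA_real_,
    n_children = n_children, child_ubi = child_ubi,
    needs_support = isTRUE(unit$needs_support),
    scenario = scenario, year = year)
  res$disposable
}

#' Gini coefficient
#'
#' Mean absolute pairwise income difference divided by twice the mean,
#' ranging from 0 (perfect equality) to 1 (perfect inequality). Computed via
#' the sorted-income identity, equivalent to the O(n^2) pairwise formula.
#'
#' @param incomes nonnegative incomes; must be nonempty and not all zero.
#' @return Gini coefficient in \[0, 1\].
#' @export
gini <- function(incomes) {
  if (length(incomes) == 0) stop_domain("gini: empty income vector")
  if (any(incomes < 0)) stop_domain("gini: negative incomes")
  if (all(incomes == 0)) stop_domain("gini: all incomes zero")
  n <- length(incomes)
  x <- sort(incomes)
  (2 * sum(seq_len(n) * x)) / (n * sum(x)) - (n + 1) / n
}

#' Fiscal balance of a scenario relative to baseline
#'
#' Government net position (taxes collected minus UBI outlays minus benefit
#' spending) of a scenario run minus the same quantity in the baseline run
#' on the same population; negative values are deficits. Operates on panels
#' produced by [run_scenario()], which carry per-year fiscal aggregates.
#'
#' @param scenario_panel,baseline_panel panels from [run_scenario()].
#' @param year optional single year; default sums all years.
#' @return GBP/year (model population scale).
#' @export
fiscal_balance <- function(scenario_panel, baseline_panel, year = NULL) {
  fs <- attr(scenario_panel, "fiscal")
  fb <- attr(baseline_panel, "fiscal")
  if (is.null(fs) || is.null(fb)) {
    stop_domain("fiscal_balance: panels must carry fiscal aggregates")
  }
  if (!identical(fs$year, fb$year)) {
    stop_domain("fiscal_balance: population/years mismatch between panels")
  }
  pos <- function(f) f$taxes - f$ubi - f$benefits
  d <- pos(fs) - pos(fb)
  if (!is.null(year)) {
    if (!year %in% fs$year) stop_domain("fiscal_balance: year not in panels")
    d[fs$year == year]
  } else {
    sum(d)
  }
}
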