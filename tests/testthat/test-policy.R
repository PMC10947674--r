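# Static tax-benefit calculator: marginal tax arithmetic, UBI payments,
# disposable income, Gini, fiscal balance.

test_that("income tax reproduces hand-computed marginal sums", {
  sc <- scenarios4()
  # at the allowance: no tax
  expect_equal(income_tax(12600, sc$baseline$tax), 0)
  expect_equal(income_tax(5000, sc$baseline$tax), 0)
  # baseline 50k: 20% of (37.7k - 12.6k) + 40% of (50k - 37.7k)
  expect_equal(income_tax(50000, sc$baseline$tax), 0.2 * 25100 + 0.4 * 12300)
  expect_equal(income_tax(50000, sc$baseline$tax), 9940)
  # full schedule, allowance + 20k: 59% to 30k, 70% above
  expect_equal(income_tax(35164.24, sc$full$tax),
               0.59 * (30000 - 15164.24) + 0.70 * 5164.24,
               tolerance = 1e-10)
  expect_equal(round(income_tax(35164.24, sc$full$tax), 2), 12368.07)
  expect_error(income_tax(-1, sc$baseline$tax), "negative")
})

test_that("income tax is continuous and nondecreasing with bracket marginal rates", {
  for (sc in scenarios4()) {
    grid <- seq(0, 160000, by = 25)
    tax <- income_tax(grid, sc$tax)
    expect_true(all(diff(tax) >= -1e-9))
    # numerical derivative equals the active bracket rate away from kinks
    mid <- grid[-1] - 12.5
    slope <- diff(tax) / 25
    th <- sc$tax$thresholds
    rate_at <- function(x) {
      i <- findInterval(x, th)
      ifelse(i == 0, 0, sc$tax$rates[pmax(i, 1)])
    }
    near_kink <- vapply(mid, function(x) any(abs(x - th) < 25), logical(1))
    expect_equal(slope[!near_kink], rate_at(mid[!near_kink]), tolerance = 1e-9)
    # continuity across kinks: jumps bounded by max rate * step
    expect_true(all(abs(diff(tax)) <= max(sc$tax$rates) * 25 + 1e-9))
  }
})

test_that("UBI payments follow the age schedule and start year", {
  sc <- scenarios4()
  expect_equal(ubi_payment(40, sc$full$ubi, 2023), 291.62)
  expect_equal(52 * ubi_payment(40, sc$full$ubi, 2023), 15164.24)
  expect_equal(ubi_payment(10, sc$full$ubi, 2023), 149.69)
  expect_equal(ubi_payment(70, sc$full$ubi, 2023), 246.16)
  expect_equal(ubi_payment(40, sc$full$ubi, 2022), 0)   # pre-implementation
  expect_equal(ubi_payment(40, NULL, 2023), 0)          # baseline: no UBI
  expect_equal(ubi_payment(40, sc$partial$ubi, 2023), 84.89)
  expect_equal(ubi_payment(10, sc$partial$ubi, 2023), 98.84)
})

test_that("disposable income handles UBI, benefits and structure errors", {
  sc <- scenarios4()
  # single adult, no earnings, Full: the annualised UBI sits inside the
  # allowance and is untaxed; no retained benefits apply
  expect_equal(disposable_income(list(gross = 0, ages = 40), sc$full, 2023),
               15164.24)
  # couple, both zero earnings, Full
  expect_equal(disposable_income(list(gross = c(0, 0), ages = c(40, 41)),
                                 sc$full, 2023), 2 * 15164.24)
  # baseline, zero earnings: stylized out-of-work benefit only
  ub <- sc$baseline$benefits$unemployment_benefit
  got <- disposable_income(list(gross = 0, ages = 40), sc$baseline, 2023)
  expect_equal(got, ub$single)
  # suspended categories contribute exactly zero: Full vs Full+ differ only
  # by the retained means-tested category
  u <- list(gross = 0, ages = 40, needs_support = TRUE)
  expect_equal(disposable_income(u, sc$full_plus, 2023) -
                 disposable_income(u, sc$full, 2023),
               sc$full_plus$benefits$means_tested$amount)
  # never below the unit's total UBI
  for (g in c(0, 5000, 50000)) {
    expect_gte(disposable_income(list(gross = g, ages = 40), sc$full, 2023),
               15164.24 - 1e-9)
  }
  expect_error(disposable_income(list(gross = c(1, 2, 3), ages = c(40, 40, 40)),
                                 sc$full, 2023), "1 or 2")
  expect_error(disposable_income(list(gross = c(1, 2), ages = 40), sc$full, 2023),
               "unresolved")
})

test_that("benefit cap binds in baseline and is suspended under UBI", {
  sc <- scenarios4()
  big_family <- list(gross = c(0, 0), ages = c(35, 34), n_children = 3L,
                     child_ages = c(2L, 5L, 9L), needs_support = TRUE)
  rules <- sc$baseline$benefits
  uncapped <- rules$unemployment_benefit$single +
    rules$unemployment_benefit$couple_supplement +
    3 * rules$unemployment_benefit$per_child +
    3 * rules$child_benefit$per_child + rules$means_tested$amount
  expect_gt(uncapped, rules$benefit_cap)
  expect_equal(disposable_income(big_family, sc$baseline, 2023),
               rules$benefit_cap)
  expect_null(sc$full_plus$benefits$benefit_cap)
})

test_that("Full UBI gains are progressive across gross-income deciles", {
  # static evaluation at fixed gross incomes: equivalised net gain of the
  # Full scenario over baseline, by decile of equivalised gross income.
  cfg <- tiny_config(3000)
  pop <- generate_population(cfg, 17)
  st <- ubisim:::build_labour_state(pop)
  couple <- st$is_couple
  set.seed(18)
  work1 <- stats::runif(nrow(st$units)) < 0.79
  work2 <- couple & stats::runif(nrow(st$units)) < 0.79
  wage <- pop$persons$wage_potential
  g1 <- wage[st$adults$person_id[st$a1]] * 40 * 52 * work1
  g2 <- ifelse(couple, wage[st$adults$person_id[st$a2]] * 40 * 52 * work2,
               NA_real_)
  age1 <- st$adults$age[st$a1]
  age2 <- ifelse(couple, st$adults$age[st$a2], NA_real_)
  kid_urow <- match(st$kid_unit, st$units$unit_id)
  eval_sc <- function(sc) {
    cub <- ubisim:::group_sum(ubisim:::ubi_annual(st$kid_age0, sc$ubi, 2023),
                              kid_urow, nrow(st$units))
    ubisim:::unit_disposable(g1, g2, age1, age2, st$units$n_children, cub,
                             st$units$needs_support, sc, 2023)$disposable
  }
  eq <- 1 + 0.5 * (st$units$n_adults - 1) + 0.3 * st$units$n_children
  gain <- (eval_sc(scenarios4()$full) - eval_sc(scenarios4()$baseline)) / eq
  gross_eq <- (g1 + ifelse(couple, g2, 0)) / eq
  dec <- cut(rank(gross_eq, ties.method = "first"), 10, labels = FALSE)
  by_dec <- tapply(gain, dec, mean)
  # lower-income units gain more: strong negative gradient, the poorest
  # half gains more than the richest half, and the top decile gains least
  # (suspended out-of-work benefits make the very bottom non-monotone)
  expect_lt(stats::cor(1:10, by_dec, method = "spearman"), -0.8)
  expect_gt(mean(by_dec[1:5]), mean(by_dec[6:10]))
  expect_equal(unname(which.min(by_dec)), 10)
  expect_lt(by_dec[10], 0)   # the top decile loses outright
  expect_gt(by_dec[1], 0)    # the bottom decile gains outright
})

test_that("gini matches the brute-force pairwise oracle", {
  expect_equal(gini(c(1, 2, 3, 4)), 0.25)
  expect_equal(gini(rep(7, 20)), 0)
  expect_equal(gini(42), 0)
  expect_error(gini(numeric(0)), "empty")
  expect_error(gini(c(0, 0)), "zero")
  set.seed(101)
  for (i in 1:100) {
    n <- sample(2:200, 1)
    x <- stats::rexp(n) * sample(c(1, 1000), 1)
    expect_equal(gini(x), gini_bruteforce(x), tolerance = 1e-10)
  }
})

test_that("fiscal balance is zero against itself, additive, and prices a pure UBI outlay", {
  cfg <- tiny_config(40)
  pop <- tiny_population(40)
  params <- point_parameter_set(cfg)
  base <- run_scenario(pop, scenarios4()$baseline, 2022:2023, params, seed = 3)
  expect_equal(fiscal_balance(base, base), 0)
  expect_equal(fiscal_balance(base, base, year = 2023), 0)
  # one adult, zero wage potential, Full vs baseline with benefits stripped
  one <- generate_population(tiny_config(1), 5)
  one$persons$wage_resid <- -30   # wage ~ 0, chooses not to work
  nb <- scenarios4()$full
  nb$benefits$maternity_sick_student$amount <- 0
  base1 <- scenarios4()$baseline
  base1$benefits <- lapply(base1$benefits, function(b) {
    if (is.list(b)) b$retained <- FALSE
    b
  })
  base1$benefits$benefit_cap <- NULL
  p_base <- run_scenario(one, base1, 2023, params, seed = 3, burn_in = 0L)
  p_full <- run_scenario(one, nb, 2023, params, seed = 3, burn_in = 0L,
                         poverty_lines = c(`2023` = 100))
  expect_equal(fiscal_balance(p_full, p_base), -15164.24)
})
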