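# Two-step mental-health module: transition detection, additive risk
# differences, realisation, effect-set differential behaviour.

state <- function(pov, emp, inc) list(in_poverty = pov, employed = emp, income = inc)

test_that("transition flags follow their definitions", {
  f <- detect_transitions(state(FALSE, TRUE, 20000), state(TRUE, TRUE, 8000))
  expect_true(f$poverty_entry); expect_false(f$poverty_exit)
  expect_false(f$persistent_poverty)
  # two consecutive years in poverty
  f <- detect_transitions(state(TRUE, FALSE, 5000), state(TRUE, FALSE, 5000))
  expect_true(f$persistent_poverty)
  expect_true(f$persistent_unemployment)
  expect_false(f$poverty_entry); expect_false(f$poverty_exit)
  # identical states and incomes: no flags, zero income change
  f <- detect_transitions(state(FALSE, TRUE, 15000), state(FALSE, TRUE, 15000))
  expect_false(any(f$poverty_entry, f$poverty_exit, f$employment_entry,
                   f$employment_exit, f$persistent_poverty,
                   f$persistent_unemployment))
  expect_equal(f$delta_log_income, 0)
  # entry and exit of the same state are never both set (vectorised sweep)
  set.seed(2)
  prev <- state(runif(200) < .5, runif(200) < .5, runif(200) * 3e4)
  cur <- state(runif(200) < .5, runif(200) < .5, runif(200) * 3e4)
  f <- detect_transitions(prev, cur)
  expect_false(any(f$poverty_entry & f$poverty_exit))
  expect_false(any(f$employment_entry & f$employment_exit))
  expect_true(all(f$persistent_poverty == (prev$in_poverty & cur$in_poverty)))
})

test_that("missing prior year yields income-only flags and a lag marker", {
  f <- detect_transitions(NULL, state(TRUE, FALSE, 4000))
  expect_false(f$has_lag)
  expect_false(any(f$poverty_entry, f$employment_exit, f$persistent_poverty))
  expect_equal(f$delta_log_income, 0)
})

test_that("income changes are measured on the floored log scale", {
  f <- detect_transitions(state(FALSE, TRUE, 10000), state(FALSE, TRUE, 20000))
  expect_equal(f$delta_log_income, log(2))
  # zero incomes are floored before the log transform
  f <- detect_transitions(state(FALSE, FALSE, 0), state(FALSE, FALSE, 100),
                          income_floor = 1)
  expect_equal(f$delta_log_income, log(100))
  expect_true(is.finite(f$delta_log_income))
})

test_that("risk differences adjust the probability additively with clipping", {
  ef <- load_effects("primary")
  flags <- detect_transitions(state(FALSE, TRUE, 1e4), state(TRUE, TRUE, 1e4))
  # additive risk difference on the probability scale
  expect_equal(adjusted_cmd_probability(0.20, flags, ef, "male"),
               0.20 + ef$male$rd_poverty_entry)
  expect_equal(adjusted_cmd_probability(0.20, flags, ef, "female"),
               0.20 + ef$female$rd_poverty_entry)
  # clipping at 1
  big <- ef; big$male$rd_poverty_entry <- 0.05
  expect_equal(adjusted_cmd_probability(0.98, flags, big, "male"), 1)
  # no flags: p0 unchanged
  none <- detect_transitions(state(FALSE, TRUE, 1e4), state(FALSE, TRUE, 1e4))
  expect_equal(adjusted_cmd_probability(0.37, none, ef, "female"), 0.37)
  expect_error(adjusted_cmd_probability(0.2, flags, ef, "other"),
               "unknown gender")
  expect_error(adjusted_cmd_probability(1.2, flags, ef, "male"), "p0")
})

test_that("sign conventions hold under the shipped defaults", {
  for (v in c("primary", "inactivity", "systematic_review")) {
    ef <- load_effects(v)
    for (g in c("male", "female")) {
      up <- c("rd_poverty_entry", "rd_employment_exit",
              "rd_persistent_poverty", "rd_persistent_unemployment")
      dn <- c("rd_poverty_exit", "rd_employment_entry")
      expect_true(all(unlist(ef[[g]][up]) > 0))
      expect_true(all(unlist(ef[[g]][dn]) < 0))
    }
  }
})

test_that("mental-health realisation is Bernoulli with a clipped parallel score", {
  out <- realize_mental_health(rep(0, 500), ghq_mu = 10, seed = 4)
  expect_false(any(out$cmd))
  out <- realize_mental_health(rep(1, 500), ghq_mu = 10, seed = 4)
  expect_true(all(out$cmd))
  out <- realize_mental_health(rep(0.3, 10000), ghq_mu = 10, seed = 5)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(mean(out$cmd) - 0.3), 3 * se)
  expect_true(all(out$ghq_likert >= 0 & out$ghq_likert <= 36))
  # continuous shift moves the mean
  a <- realize_mental_health(rep(0.3, 5000), 15, continuous_shift = 0, seed = 6)
  b <- realize_mental_health(rep(0.3, 5000), 15, continuous_shift = 2, seed = 6)
  expect_equal(mean(b$ghq_likert) - mean(a$ghq_likert), 2, tolerance = 0.05)
})

test_that("swapping to the inactivity set changes only employment channels", {
  pr <- load_effects("primary"); inact <- load_effects("inactivity")
  set.seed(31)
  n <- 400
  prev <- state(runif(n) < .3, runif(n) < .8, runif(n) * 3e4)
  cur <- state(runif(n) < .2, runif(n) < .75, runif(n) * 3e4)
  flags <- detect_transitions(prev, cur)
  gender <- sample(c("male", "female"), n, replace = TRUE)
  p0 <- runif(n, 0.05, 0.6)
  p_pr <- adjusted_cmd_probability(p0, flags, pr, gender)
  p_in <- adjusted_cmd_probability(p0, flags, inact, gender)
  emp_channel <- flags$employment_entry | flags$employment_exit |
    flags$persistent_unemployment
  # poverty-only channels are bit-identical; employment channels differ
  expect_identical(p_pr[!emp_channel], p_in[!emp_channel])
  expect_false(isTRUE(all.equal(p_pr[emp_channel], p_in[emp_channel])))
})
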