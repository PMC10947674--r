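# Synthetic population generator: structure, determinism, sampling bounds,
# parameter draws, baseline mental health.

test_that("generation is deterministic and empty input yields an empty population", {
  p0 <- generate_population(tiny_config(0), 1)
  expect_equal(nrow(p0$persons), 0)
  expect_equal(nrow(p0$units), 0)
  a <- generate_population(tiny_config(400), 7)
  b <- generate_population(tiny_config(400), 7)
  expect_identical(a, b)
  c_ <- generate_population(tiny_config(400), 8)
  expect_false(identical(a$persons$age, c_$persons$age))
})

test_that("population structure honours benefit-unit invariants", {
  pop <- tiny_population(2000)
  per <- pop$persons; un <- pop$units
  adults <- per[per$is_adult, ]
  expect_true(all(adults$age >= 25 & adults$age <= 64))
  kids <- per[!per$is_adult, ]
  expect_true(all(kids$age >= 0 & kids$age <= 15))
  # unit sizes match member rows
  n_ad <- table(factor(adults$unit_id, levels = un$unit_id))
  expect_equal(as.integer(n_ad), un$n_adults)
  n_k <- table(factor(kids$unit_id, levels = un$unit_id))
  expect_equal(as.integer(n_k), un$n_children)
  expect_true(all(un$n_adults %in% 1:2))
  # lone parent: exactly one adult and at least one child
  expect_true(all(un$n_adults[un$is_lone_parent] == 1))
  expect_true(all(un$n_children[un$is_lone_parent] >= 1))
  # couples are one male, one female
  cu <- un$unit_id[un$n_adults == 2]
  g <- table(adults$unit_id[adults$unit_id %in% cu], adults$gender[adults$unit_id %in% cu])
  expect_true(all(g == 1))
  expect_true(all(per$wage_potential[per$is_adult] > 0))
})

test_that("education shares land within binomial sampling bounds", {
  n <- 10000
  pop <- generate_population(tiny_config(n), 3)
  adults <- pop$persons[pop$persons$is_adult, ]
  shares <- tiny_config()$education_shares
  for (lvl in names(shares)) {
    p <- shares[[lvl]]
    se <- sqrt(p * (1 - p) / nrow(adults))
    expect_lt(abs(mean(adults$education == lvl) - p), 3 * se + 1e-12)
  }
})

test_that("wage model follows the exponentiated linear index", {
  cfg <- tiny_config()
  params <- point_parameter_set(cfg)
  # all coefficients zero, zero noise: GBP 1.00/hour
  params0 <- params
  params0$wage <- list(intercept = 0, medium = 0, high = 0, male = 0, age = 0,
                       sigma = 0, heckman_delta = 0)
  df <- data.frame(age = c(30, 50), gender = c("male", "female"),
                   education = c("low", "high"))
  expect_equal(potential_wage(df, params0, 1), c(1, 1))
  # education effect of +0.5 multiplies wages by exp(0.5)
  params5 <- params0
  params5$wage$high <- 0.5
  w <- potential_wage(data.frame(age = c(40, 40), gender = c("female", "female"),
                                 education = c("low", "high")), params5, 1)
  expect_equal(w[2] / w[1], exp(0.5))
  # deterministic given the seed
  dfl <- data.frame(age = 40, gender = "male", education = "medium")
  expect_identical(potential_wage(dfl, params, 9), potential_wage(dfl, params, 9))
  # configured gradient: mean log wage strictly increasing in education
  pop <- tiny_population(5000)
  ad <- pop$persons[pop$persons$is_adult, ]
  mlw <- tapply(log(ad$wage_potential), ad$education, mean)
  expect_lt(mlw[["low"]], mlw[["medium"]])
  expect_lt(mlw[["medium"]], mlw[["high"]])
})

test_that("parameter draws honour the covariance configuration", {
  cfg <- tiny_config()
  # zero covariance: draws equal the point estimates exactly
  cfg0 <- cfg
  cfg0$parameter_covariances <- lapply(cfg$parameter_covariances, function(b) b * 0)
  expect_identical(draw_parameter_set(cfg0, 5), point_parameter_set(cfg0))
  # same seed: identical draw; different seed: different draw
  expect_identical(draw_parameter_set(cfg, 5), draw_parameter_set(cfg, 5))
  d1 <- draw_parameter_set(cfg, 5); d2 <- draw_parameter_set(cfg, 6)
  expect_false(identical(d1$wage$intercept, d2$wage$intercept))
  # 1000 draws of a scalar with variance sigma^2: sample variance within
  # 3 Monte-Carlo standard errors (chi-square sampling bounds)
  sigma <- 0.015   # configured sd of the male wage coefficient
  draws <- vapply(1:1000, function(s) draw_parameter_set(cfg, s)$wage$male,
                  numeric(1))
  se_var <- sigma^2 * sqrt(2 / (1000 - 1))
  expect_lt(abs(stats::var(draws) - sigma^2), 3 * se_var)
  expect_lt(abs(mean(draws) - cfg$wage_coefficients$male), 3 * 0.015 / sqrt(1000))
})

test_that("baseline mental health follows the Step-1 logistic model", {
  cfg <- tiny_config(10000)
  pop <- generate_population(cfg, 21)
  params <- point_parameter_set(cfg)
  # all coefficients zero: probability one half for everyone
  p0 <- params
  p0$mh_binary <- list(intercept = 0, female = 0, low = 0, medium = 0,
                       age45 = 0, children = 0)
  out <- assign_baseline_mental_health(pop, p0, 1)
  probs <- out$persons$p_cmd[out$persons$is_adult]
  expect_true(all(probs == 0.5))
  # intercept log(0.25/0.75): probability 0.25 by inverse-logit arithmetic
  p25 <- p0
  p25$mh_binary$intercept <- log(0.25 / 0.75)
  out <- assign_baseline_mental_health(pop, p25, 1)
  expect_equal(unique(out$persons$p_cmd[out$persons$is_adult]), 0.25)
  # p = 0.2 for everyone: observed prevalence within 3 binomial SE
  p20 <- p0
  p20$mh_binary$intercept <- stats::qlogis(0.2)
  out <- assign_baseline_mental_health(pop, p20, 2)
  cmd <- out$persons$cmd[out$persons$is_adult]
  se <- sqrt(0.2 * 0.8 / length(cmd))
  expect_lt(abs(mean(cmd) - 0.2), 3 * se)
  # GHQ Likert scores live on [0, 36]
  out <- assign_baseline_mental_health(pop, params, 3)
  ghq <- out$persons$ghq_likert[out$persons$is_adult]
  expect_true(all(ghq >= 0 & ghq <= 36))
})
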