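---
title: "Modelling UBI and population mental health: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling UBI and population mental health: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ubisim)
```

# The question and the modelling strategy

A Universal Basic Income changes mental health, in this model, only through
material pathways: income levels, poverty transitions, and employment
transitions. `ubisim` evolves a synthetic working-age population (adults
25–64 in benefit units) in one-year steps from 2022 to 2026, introduces a
UBI in 2023 under three counterfactual tax/benefit systems, and propagates
the resulting economic changes into the probability of likely common mental
disorder (CMD, GHQ-12 caseness) and a continuous GHQ Likert score. The
pipeline is deliberately self-contained: the population is parametric and
generated in code, so every stage is testable without access to the
proprietary household surveys such models are normally estimated on. The
cost of that choice is that all coefficients are *illustrative defaults
calibrated to published aggregates*, not estimates — reproduced below.

# The synthetic population

`generate_population()` builds benefit units first: a configurable share of
adults live in couples (default 64%), couple units have children with
probability 0.55, single units with probability 0.22 (lone parents, 86%
female). Family sizes are 1–3 children with probabilities 0.45/0.40/0.15.
Adult ages are uniform on 25–64 and children 0–15: the real age structure
is mildly non-uniform, but none of the reported outcomes depend on its
shape, and uniform is transparent. Education (low/medium/high =
0.25/0.40/0.35) is assigned independently of partnership.

Hourly wage potential is log-linear:
`log w = 2.35 + 0.22·medium + 0.52·high + 0.12·male + 0.004·(age − 45) + ε`,
`ε ~ N(0, 0.42²)` drawn once per adult (a permanent residual; the
deterministic part is re-evaluated as people age). A Heckman-style
inverse-Mills selection term is implemented (`heckman_delta`) but off by
default because no selection coefficients are available to populate it.

What the generator does *not* emulate: survey weights, attrition, panel
conditioning, immigration, births, deaths and partnership changes — the
population is closed over the 5-year horizon. Passing tests therefore show
the *mechanisms* behave correctly under these study conditions, not that
the model is calibrated to any particular real cohort.

# Tax, UBI and stylized benefits

`income_tax()` is an ordinary marginal-bracket calculator. The shipped
schedules use the published rounded thresholds (£12.6k/£37.7k/£125.1k at
20/40/45% for the baseline; £12.6k/£30k/£50k at 20/45/60% for Partial;
£15,164.24/£30k/£50k at 59/70/85% for Full and Full+). UBI is taxable, and
in the Full scenarios the personal allowance equals the annualised adult
payment (52 × £291.62 = £15,164.24), so a non-working adult receives the
UBI untaxed. Weeks per year are fixed at 52.

The UK benefit rulebook is out of scope; benefits are stylized categories
with flat annual amounts and simple earnings cutoffs, each retained or
suspended per scenario: child benefit (£4,600/child), out-of-work support
(£5,000 + £4,300 couple + £2,000/child, paid when unit earnings are zero),
in-work support (£2,800 + £1,400/child below £17k earnings), a means-tested
category standing in for caring/childcare/disability/housing support
(£6,600 for the 55% of units flagged as having such needs, below £16k
earnings), and a maternity/sick/student category (retained everywhere,
zero by default). A benefit cap (£22,020) binds in the baseline only. The
amounts were chosen, jointly with the preference parameters, so that the
*baseline* reproduces ~9% poverty and the *Partial* UBI roughly replaces
existing benefits at the bottom of the distribution (its per-adult payment
of £4,414/year is close to the out-of-work amount it suspends).

# Labour supply

Benefit units choose joint weekly hours from {0, 10, 20, 30, 40} per adult
by maximising

U = 0.70·log(max(disposable, £100)) − 0.004·hours
  + attachment·1(working) + 0.60·1(status kept) + Gumbel(0, 1),

where `attachment = −0.24` (−1.20 extra for women in units with children,
standing in for childcare costs) and the inertia term rewards keeping last
year's employment status. Gumbel shocks per joint option give closed-form
multinomial-logit probabilities, which the engine uses both for simulation
and for expected-employment calibration.

Three choices deserve comment:

- **The income weight is small relative to the taste noise.** This is the
  calibration's key degree of freedom: a liveable UBI roughly triples
  out-of-work income, and with a large income weight the simulated
  employment fall exceeds 15 pp — far beyond anything observed in
  UBI-like interventions. The shipped weight produces a ~4 pp fall for
  Full/Full+ and a baseline rate near 79%, i.e. realistically inelastic
  aggregate labour supply.
- **Employment-state inertia.** An i.i.d. logit would churn ~30% of
  workers per year; actual labour-market transitions are far rarer, and
  the mental-health module is driven by transitions. The inertia bonus
  keeps annual transition rates near 10% while leaving the stationary
  employment level to the static utilities. Two unrecorded burn-in years
  are simulated before 2022 so the recorded panel starts near the
  stationary state and 2022 has proper lagged states.
- **Couples are unitary** with independent shocks per joint option; one
  joint choice maximises the unit's utility.

The fixed-employment sensitivity mode (`sens1_fixed_employment`)
recalibrates an additive utility offset on working options each
intervention year by bisection until the *expected* scenario employment
rate matches the realised baseline rate for that year (tolerance 0.1 pp,
checked on the logit probabilities; the realised rate then differs only by
binomial noise).

# The mental-health module

Step 1 assigns each adult a baseline CMD probability from a logistic model
(intercept −1.583; female +0.10; low education +0.285, medium +0.158;
age ≥ 45 −0.02; children +0.04), giving ~20% prevalence with an education
gradient whose panel RII is ≈ 1.33 after the employment gradient feeds in.
A parallel linear model (mean ≈ 10–12, SD 4.5, clipped to 0–36) drives the
continuous GHQ score. The binary and continuous outcomes are simulated as
parallel processes sharing the same transition inputs — the flag is not a
threshold on the score, mirroring their treatment as separate analyses.

Step 2 adds gender-specific risk differences on the *probability* scale
(the natural scale for risk differences; a log-odds alternative would make
the same estimate act differently at different baselines), clipped to
[0, 1]. The shipped primary set is:

| channel | male | female |
|---|---|---|
| employment exit / entry | ±0.20 | ±0.14 |
| poverty entry / exit | ±0.022 | ±0.0154 |
| persistent (2-year) poverty | +0.022 | +0.0154 |
| persistent unemployment | +0.07 | +0.049 |
| per unit Δlog income | −0.002 | −0.003 |

Poverty effects are exactly 11% of employment effects per gender — the
empirical ratio the module is built around — and effects are memoryless
beyond the two-year persistence terms (only short-term, 1-year effects are
modelled). The magnitudes were calibrated so the 2023 Full+ contrast lands
inside the published uncertainty of both the primary analysis (positive,
a few tenths of a percentage point) and the fixed-employment sensitivity
(negative). Income floors at £1/year avoid −∞ under the log transform.
Two alternative sets ship as YAML: `inactivity` (employment channels
reduced to economic-inactivity magnitudes; poverty channels bit-identical
to primary) and `systematic_review` (smaller magnitudes throughout).

# Poverty, incomes and inequality

Poverty is assessed at the benefit-unit level before housing costs: a unit
is poor when its equivalised disposable income falls below 60% of the
*baseline scenario's* median for that year. Anchoring the line to baseline
is essential — a Full UBI raises the contemporaneous median so much that a
relative line would mechanically re-create poverty. Each replicate's
baseline run computes its lines; counterfactuals reuse them.

Equivalisation uses the OECD-modified scale (1 + 0.5 per additional adult
+ 0.3 per child); a strict per-head split is available
(`equivalence_scale: percapita`) but cannot reach single-digit baseline
poverty, because single-earner families then dominate the poor. The
"median income" metric reported in tables is benefit-unit disposable
income per adult — an individual-level income concept — while poverty uses
the equivalised measure; both are documented columns of the panel.

RII and SII are computed by weighted least squares of education-group CMD
prevalence on ridit midpoints (cumulative share of more-educated groups
plus half the own share; x = 0 is the most-educated extreme), weights equal
to group shares. RII is fitted(1)/fitted(0) from the identity-link fit, not
exp(slope) of a log-link model — it is the ratio the verbal definition
describes, and the convention is switch-free and testable against a
normal-equations oracle. If fitted(0) ≤ 0 the RII is undefined and returned
as `NA` with a warning (the SII is still valid). Case counts scale
prevalence differences to the Q4-2022 UK working-age population
(41,566,000), rounded to the nearest case.

# Uncertainty

Each replicate draws a fresh parameter set (multivariate normal around the
point estimates with configured, default-diagonal covariance blocks; zero
covariance returns the point estimates exactly) and a fresh population, and
runs all scenarios with shared per-year random streams (common random
numbers), which makes paired scenario-minus-baseline differences much less
noisy than independent streams. Summaries are medians with 95% uncertainty
intervals from the 2.5th/97.5th percentiles, interpolated linearly between
order statistics (index = (n−1)p + 1). Both the percentile interval of
paired per-replicate differences (the headline, the only well-defined
per-difference interval) and the difference of medians are reported.
Whether the population should be redrawn per replicate is genuinely open;
the default redraws it (capturing population sampling uncertainty), and
`redraw_population = FALSE` freezes it.

# Problem sizes

The shipped analysis scripts and the acceptance script run at desk scale:
5,000–10,000 adults and 30–50 replicates, which reproduce all qualitative
contrasts with uncertainty intervals a little wider than a full-scale run.
The study-scale configuration (25,000 adults, 1,000 replicates) is a
config change (`n_persons`, `n_reps`) and runs in a few hours on one CPU.

# Numerical and degenerate-input conventions

Ties in the argmax over choice options are broken by first index (measure
zero under continuous shocks); empty populations yield empty panels; empty
strata yield explicit `NA`, never silent zeros; the Gini is undefined for
empty or all-zero incomes (error); bisection for the employment offset
expands its bracket once and then fails loudly; boundary employment
targets (0% or 100%) are rejected as unattainable for a logit. All seeds
derive from a single integer via a fixed mixing function, and every run is
byte-identical given (configuration, seed), independent of execution
order of replicates.

# Known limitations

Beyond the generator's simplifications listed above: no macroeconomic
feedback (wages and prices are exogenous); no psychosocial pathways from
UBI to mental health (only income, poverty, employment), so effects
operating through perceived security are not captured; no mental-health
feedback onto labour supply; a stylized benefit system rather than the UK
rulebook; pensioner payments encoded but pensioners not simulated (the
analysis population is 25–64, and people ageing past 64 mid-simulation are
retained in their units but excluded from outcome denominators). Gains and
losses by income decile are progressive overall but not strictly monotone
at the very bottom, where suspended out-of-work benefits partially offset
the UBI — as in real tax-benefit reforms. Fiscal balances cover only the
simulated working-age population and the stylized benefits, so they are
not comparable to whole-economy costings.
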