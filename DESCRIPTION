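Package: ubisim
Title: Dynamic Microsimulation of Universal Basic Income, Poverty and
    Population Mental Health
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale dynamic microsimulation of Universal Basic Income
    (UBI) reform in a synthetic UK-like working-age population. Generates
    benefit units of adults aged 25-64, evolves them annually through a
    static tax-benefit calculator, a discrete-choice random-utility labour
    supply module and a two-step causal mental-health module (demographic
    baseline risk of common mental disorder adjusted by gender-specific risk
    differences for poverty and employment transitions). Computes poverty
    against baseline-anchored lines, Gini coefficients, relative and slope
    indices of inequality, prevalence-to-case-count conversions, and
    Monte-Carlo uncertainty intervals across replicates with common random
    numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
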