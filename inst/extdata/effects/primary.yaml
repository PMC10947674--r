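# Primary effect set for Step 2 of the mental health module: gender-specific
# risk differences (probability points, signed) for the effect of economic
# transitions on the probability of likely common mental disorder, plus
# parallel effects on the continuous GHQ Likert score. Values are
# illustrative defaults calibrated so that poverty-transition effects are
# exactly 11% of the size of employment-transition effects for each gender.
variant: primary
male:
  rd_poverty_entry: 0.022
  rd_poverty_exit: -0.022
  rd_employment_exit: 0.20
  rd_employment_entry: -0.20
  rd_persistent_poverty: 0.022
  rd_persistent_unemployment: 0.07
  beta_log_income: -0.002
  likert:
    poverty_entry: 0.198
    poverty_exit: -0.198
    employment_exit: 1.80
    employment_entry: -1.80
    persistent_poverty: 0.198
    persistent_unemployment: 0.63
    beta_log_income: -0.02
female:
  rd_poverty_entry: 0.0154
  rd_poverty_exit: -0.0154
  rd_employment_exit: 0.14
  rd_employment_entry: -0.14
  rd_persistent_poverty: 0.0154
  rd_persistent_unemployment: 0.049
  beta_log_income: -0.003
  likert:
    poverty_entry: 0.139
    poverty_exit: -0.139
    employment_exit: 1.26
    employment_entry: -1.26
    persistent_poverty: 0.139
    persistent_unemployment: 0.44
    beta_log_income: -0.03
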