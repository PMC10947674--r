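# Alternative effect set with magnitudes sourced from the systematic-review
# literature on income/employment transitions and mental health: smaller
# effects overall for both channels.
variant: systematic_review
male:
  rd_poverty_entry: 0.006
  rd_poverty_exit: -0.006
  rd_employment_exit: 0.07
  rd_employment_entry: -0.07
  rd_persistent_poverty: 0.006
  rd_persistent_unemployment: 0.02
  beta_log_income: -0.001
  likert:
    poverty_entry: 0.055
    poverty_exit: -0.055
    employment_exit: 0.63
    employment_entry: -0.63
    persistent_poverty: 0.055
    persistent_unemployment: 0.18
    beta_log_income: -0.01
female:
  rd_poverty_entry: 0.005
  rd_poverty_exit: -0.005
  rd_employment_exit: 0.055
  rd_employment_entry: -0.055
  rd_persistent_poverty: 0.005
  rd_persistent_unemployment: 0.016
  beta_log_income: -0.0012
  likert:
    poverty_entry: 0.045
    poverty_exit: -0.045
    employment_exit: 0.50
    employment_entry: -0.50
    persistent_poverty: 0.045
    persistent_unemployment: 0.14
    beta_log_income: -0.012
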