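# Alternative effect set treating moves out of employment as voluntary
# economic inactivity (less detrimental to mental health). Poverty channels
# are identical to the primary set; only employment-transition channels
# differ.
variant: inactivity
male:
  rd_poverty_entry: 0.022
  rd_poverty_exit: -0.022
  rd_employment_exit: 0.04
  rd_employment_entry: -0.04
  rd_persistent_poverty: 0.022
  rd_persistent_unemployment: 0.015
  beta_log_income: -0.002
  likert:
    poverty_entry: 0.198
    poverty_exit: -0.198
    employment_exit: 0.35
    employment_entry: -0.35
    persistent_poverty: 0.198
    persistent_unemployment: 0.13
    beta_log_income: -0.02
female:
  rd_poverty_entry: 0.0154
  rd_poverty_exit: -0.0154
  rd_employment_exit: 0.03
  rd_employment_entry: -0.03
  rd_persistent_poverty: 0.0154
  rd_persistent_unemployment: 0.012
  beta_log_income: -0.003
  likert:
    poverty_entry: 0.139
    poverty_exit: -0.139
    employment_exit: 0.26
    employment_entry: -0.26
    persistent_poverty: 0.139
    persistent_unemployment: 0.10
    beta_log_income: -0.03
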