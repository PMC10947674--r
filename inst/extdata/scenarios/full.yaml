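# Scenario 3 - Full UBI: payment at the Minimum Income Standard; personal
# allowance equals the annualised adult UBI (52 x 291.62 = 15164.24); all
# means-tested and out-of-work benefits suspended.
name: full
tax:
  allowance: 15164.24
  thresholds: [15164.24, 30000, 50000]
  rates: [0.59, 0.70, 0.85]
ubi:
  weekly_child: 149.69
  weekly_adult: 291.62
  weekly_pensioner: 246.16
  start_year: 2023
  pension_age: 66
benefits:
  benefit_cap: ~
  child_benefit:        {retained: no, per_child: 4600, earnings_cutoff: 50000}
  unemployment_benefit: {retained: no, single: 5000, couple_supplement: 4300, per_child: 2000}
  income_support:       {retained: no, amount: 2800, per_child: 1400, earnings_cutoff: 17000}
  means_tested:         {retained: no, amount: 6600, earnings_cutoff: 16000}
  maternity_sick_student: {retained: yes, amount: 0}
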