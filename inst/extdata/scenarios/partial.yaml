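# Scenario 2 - Partial UBI: payment at roughly the level of existing
# benefits; raised upper tax rates; child benefit, income support and
# unemployment benefits suspended; means-tested support retained.
name: partial
tax:
  allowance: 12600
  thresholds: [12600, 30000, 50000]
  rates: [0.20, 0.45, 0.60]
ubi:
  weekly_child: 98.84
  weekly_adult: 84.89
  weekly_pensioner: 196.53
  start_year: 2023
  pension_age: 66
benefits:
  benefit_cap: ~
  child_benefit:        {retained: no, per_child: 4600, earnings_cutoff: 50000}
  unemployment_benefit: {retained: no, single: 5000, couple_supplement: 4300, per_child: 2000}
  income_support:       {retained: no, amount: 2800, per_child: 1400, earnings_cutoff: 17000}
  means_tested:         {retained: yes, amount: 6600, earnings_cutoff: 16000}
  maternity_sick_student: {retained: yes, amount: 0}
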