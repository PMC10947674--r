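# Scenario 1 - Baseline: planned UK tax/benefit policies, no UBI.
name: baseline
tax:
  allowance: 12600
  thresholds: [12600, 37700, 125100]
  rates: [0.20, 0.40, 0.45]
ubi: ~
benefits:
  benefit_cap: 22020
  child_benefit:        {retained: yes, per_child: 4600, earnings_cutoff: 50000}
  unemployment_benefit: {retained: yes, single: 5000, couple_supplement: 4300, per_child: 2000}
  income_support:       {retained: yes, amount: 2800, per_child: 1400, earnings_cutoff: 17000}
  means_tested:         {retained: yes, amount: 6600, earnings_cutoff: 16000}
  maternity_sick_student: {retained: yes, amount: 0}
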