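source: synthetic (seed 20)
ysd_cap: 14
files:
  prevalence: prevalence.tsv
  transitions: transitions.tsv
  tests: test_performance.tsv
  mortality: mortality_all_cause.tsv
  crc_mortality: crc_mortality.tsv
  life_expectancy: life_expectancy.tsv
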