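variant: isolation_admixture
ne: 40000
c: 0.05
split_years: 400
bottleneck_start_years: 13000
join_years: 14000
bottleneck_factor: 10
generation_time_years: 3
sampling:
  modern_count: 299
  ancient_count: 13
  ancient_age_years: 1000
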