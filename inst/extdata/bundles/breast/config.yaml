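cancer: breast
# fraction of incidence attributable to measured risk-factor elevation;
# deflates registry rates to reference-profile baseline hazards
attributable_risk: 0.52
files:
  rr_model: rr_model.yaml
  incidence_raw: incidence_raw.csv
  # SYNTHETIC: built from US life-table all-cause mortality for white women
  # (1992-2006 era) minus deaths from the three modelled cancers; stands in
  # for registry competing-mortality rates
  competing_mortality: competing_mortality_synthetic.csv
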