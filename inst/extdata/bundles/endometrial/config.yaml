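cancer: endometrial
attributable_risk: 0.81
files:
  rr_model: rr_model.yaml
  incidence_raw: incidence_raw.csv
  competing_mortality: competing_mortality_synthetic.csv   # SYNTHETIC stand-in, see breast/config.yaml
  # DERIVED: intact-uterus proportion back-solved bin-wise from the published
  # raw / hysterectomy-corrected incidence pairs
  organ_prevalence: intact_organ_prevalence_derived.csv
  # SYNTHETIC: hysterectomy hazard derived from the prevalence log-gradient
  organ_removal_rates: organ_removal_rates_synthetic.csv
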