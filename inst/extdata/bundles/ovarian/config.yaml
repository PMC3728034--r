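cancer: ovarian
attributable_risk: 0.43
files:
  rr_model: rr_model.yaml
  incidence_raw: incidence_raw.csv
  competing_mortality: competing_mortality_synthetic.csv   # SYNTHETIC stand-in, see breast/config.yaml
  # DERIVED: intact-ovaries proportion back-solved bin-wise from the published
  # raw / oophorectomy-corrected incidence pairs
  organ_prevalence: intact_organ_prevalence_derived.csv
  # SYNTHETIC: bilateral-oophorectomy hazard from the prevalence log-gradient
  organ_removal_rates: organ_removal_rates_synthetic.csv
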