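# Endometrial cancer multiplicative relative-risk model.
# Lowest-risk category is the reference (implied RR 1.0) throughout; note the
# references here: current smokers, OC users of 1+ years, and parity 3+ are
# the lowest-risk groups for this cancer.
cancer: endometrial
factors:
  - name: bmi
    mode: trend
    categories: ["<25", "25-<30", "30-<35", "35-<40", "40+"]
    rr: 1.72
  - name: oc_use                # oral contraceptive use
    mode: per_category
    categories: ["1+y", "<1y"]
    rr: [1.44]
  - name: mht_use               # any menopausal hormone therapy, duration
    mode: trend
    categories: ["never", "<10y", "10+y"]
    rr: 1.15
  - name: parity
    mode: trend
    categories: ["3+", "1-2", "0"]
    rr: 1.21
  - name: age_menopause
    mode: trend
    categories: ["<50", "50-54", "55+"]
    rr: 1.26
    special_levels:
      NA/missing: 1.29
  - name: smoking
    mode: per_category
    categories: ["current", "never", "former"]
    rr: [1.47, 1.21]
interactions:
  # extra MHT duration risk among lean women (BMI < 25 kg/m^2)
  - when_factor: bmi
    when_level: 0
    target_factor: mht_use
    multiplier: 1.61
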