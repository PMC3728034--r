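# Breast cancer multiplicative relative-risk model.
# Lowest-risk category is the reference (implied RR 1.0) throughout.
cancer: breast
factors:
  - name: bmi
    mode: trend
    categories: ["<25", "25-<30", "30-<35", "35+"]
    rr: 1.09
  - name: ep_mht_use            # estrogen + progestin menopausal hormone therapy
    mode: trend
    categories: ["never", "<10y", "10+y"]
    rr: 1.40
  - name: other_mht_use
    mode: indicator
    categories: ["no", "yes"]
    rr: 1.16
  - name: age_first_birth
    mode: trend
    categories: ["<25", "25-29", "30+"]
    rr: 1.17
  - name: parity                # nulliparous is the elevated-risk category
    mode: indicator
    categories: ["1+", "0"]
    rr: 1.32
  - name: age_menopause
    mode: trend
    categories: ["<50", "50-54", "55+"]
    rr: 1.18
    special_levels:
      NA/missing: 1.17          # premenopausal or unknown age at menopause
  - name: bbd                   # benign breast disease / breast biopsy
    mode: indicator
    categories: ["no", "yes"]
    rr: 1.40
  - name: family_history        # first-degree breast or ovarian cancer
    mode: indicator
    categories: ["no", "yes"]
    rr: 1.39
  - name: alcohol
    mode: trend
    categories: ["0", "<1", "1+"]
    rr: 1.12
interactions: []
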