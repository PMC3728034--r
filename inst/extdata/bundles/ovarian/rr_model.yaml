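# Ovarian cancer multiplicative relative-risk model.
cancer: ovarian
factors:
  - name: oc_use
    mode: per_category
    categories: ["1+y", "<1y"]
    rr: [1.36]
  - name: mht_use
    mode: trend
    categories: ["never", "<10y", "10+y"]
    rr: 1.26
  - name: parity
    mode: trend
    categories: ["3+", "1-2", "0"]
    rr: 1.25
  - name: family_history
    mode: indicator
    categories: ["no", "yes"]
    rr: 1.27
interactions: []
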