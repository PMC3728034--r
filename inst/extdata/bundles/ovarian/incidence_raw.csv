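age_lo,age_hi,rate_per_100k
50,55,25.93
55,60,33.5
60,65,43.47
65,70,49.06
70,75,56.15
75,80,60.25
80,85,62.68
85,90,54.61
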