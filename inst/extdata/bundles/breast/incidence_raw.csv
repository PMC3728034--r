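age_lo,age_hi,rate_per_100k
50,55,272.42
55,60,338.62
60,65,410.08
65,70,465.29
70,75,499.4
75,80,518.48
80,85,491.45
85,90,408.84
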