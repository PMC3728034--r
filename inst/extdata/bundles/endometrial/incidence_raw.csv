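age_lo,age_hi,rate_per_100k
50,55,50.5
55,60,77.5
60,65,97.44
65,70,106.5
70,75,109.02
75,80,106.05
80,85,96.76
85,90,69.26
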