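age_lo,age_hi,rate_per_100k
50,55,1726.35
55,60,1714.35
60,65,281.26
65,70,171.51
70,75,188.04
75,80,0
80,85,0
85,90,0
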