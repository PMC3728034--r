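age_lo,age_hi,rate_per_100k
50,55,300
55,60,490
60,65,800
65,70,1300
70,75,2090
75,80,3480
80,85,5800
85,90,9700
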