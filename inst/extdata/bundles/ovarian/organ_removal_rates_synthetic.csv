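age_lo,age_hi,rate_per_100k
50,55,4.58
55,60,1868.12
60,65,1078.54
65,70,0
70,75,782.58
75,80,37.5
80,85,0
85,90,0
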