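age_lo,age_hi,proportion_with_organ
50,55,0.6623819517
55,60,0.6076048608
60,65,0.5576923077
65,70,0.5499044767
70,75,0.5452090418
75,80,0.5401069519
80,85,0.5614157238
85,90,0.5865018206
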