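age_lo,age_hi,proportion_with_organ
50,55,0.8052795031
55,60,0.8050949291
60,65,0.7332995951
65,70,0.6948024359
70,75,0.7679157549
75,80,0.7384483393
80,85,0.7370649106
85,90,0.8388632873
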