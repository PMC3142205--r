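age_group,share
0-14,0.158
15-19,0.058
20-29,0.152
30-39,0.152
40-49,0.150
50-59,0.128
60-69,0.092
70-79,0.068
80+,0.042
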