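category	unique_control_pct	total_control_pct	unique_treated_pct	total_treated_pct
Total	100.00	100.00	100.00	100.00
miRNA	1.53	23.03	1.15	34.70
rRNA	1.22	3.15	1.33	3.57
snRNA	0.04	0.02	0.04	0.02
snoRNA	0.02	0.01	0.01	0.01
tRNA	0.26	13.86	0.26	3.81
unann	96.93	59.92	97.21	57.89
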