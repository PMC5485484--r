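category	unique_control_pct	total_control_pct	unique_treated_pct	total_treated_pct
rRNA	0.09	0.32	0.09	0.22
tRNA	0.02	0.06	0.02	0.03
snRNA	0.06	0.05	0.08	0.07
snoRNA	0.05	0.05	0.06	0.07
polyN	0.15	0.10	0.18	0.15
cDNA_sense	32.17	35.46	31.83	36.11
cDNA_antisense	34.59	40.21	32.98	38.68
other	32.85	23.75	34.76	24.66
Total	100.00	100.00	100.00	100.00
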