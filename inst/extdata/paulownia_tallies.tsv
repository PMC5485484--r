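quantity	value
raw_reads	23221177
high_quality_reads	23168277
clean_reads	23040002
clean_reads_control	11262450
clean_reads_treated	11777552
unann_unique_control	3122830
unann_unique_treated	3089262
unann_unique_pooled	6212092
conserved_mirnas	32
novel_mirnas	75
total_mirnas	107
novel_5p	34
novel_3p	41
conserved_with_star	20
novel_with_star	12
de_mirnas	77
de_up	17
de_down	60
sig_mirnas	60
sig_up	16
sig_down	44
target_genes	42
cleavage_sites	47
sites_cat0	1
sites_cat1	1
sites_cat2	10
sites_cat3	1
sites_cat4	34
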