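category	unique_control	total_control	unique_treated	total_treated
Total	3221622	11262450	3177839	11777552
miRNA	49384	2593930	36471	4086959
rRNA	39391	355152	42204	420074
snRNA	1256	2508	1288	2723
snoRNA	484	1061	441	686
tRNA	8277	1561078	8173	448506
unann	3122830	6748721	3089262	6818604
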