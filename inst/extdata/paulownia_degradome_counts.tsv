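category	unique_control	total_control	unique_treated	total_treated
rRNA	8193	73628	10416	59240
tRNA	2213	12546	2123	8211
snRNA	5867	12247	8846	18564
snoRNA	4519	12313	6430	19028
polyN	13943	22872	19312	39525
cDNA_sense	2926724	8086336	3496643	9535686
cDNA_antisense	3146670	9168559	3622646	10214034
other	2988689	5414596	3817634	6510491
Total	9096818	22803097	10984050	26404779
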