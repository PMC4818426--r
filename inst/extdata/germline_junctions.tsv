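site	left_flank	right_flank	chromosome	locus
1	aaatatttaccaagcaac	caagcaacacgttcagtg	8	intron_gfra2
2	ataatttcctcttatttg	cttatttgcatgtcagat	13	intergenic
3	cgcatgctaacttataga	cttatagaggaggtgccc	8	exon_fb79a07
4	aaacgttcctcctaacac	cctaacacagttagatgg	3	intergenic
5	caacacatgactcgttgg	ctcgttggccatatgcta	15	intergenic
6	gggaatatgtgttattaa	gttattaactgcgtccca	4	repetitive
7	agctgtctcttctgtgtc	tctgtgtcattcagtctc	3	intron_LOC557901
8	tgtcagagatctaggtca	ctaggtcagatggaggaa	25	intergenic
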