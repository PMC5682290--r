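name	feature	set1	n1	size1	set2	n2	size2
editing_ssc3utr_rs50	editing_sites	SSC_3UTR_rs50	1479	2274485	nonSSC_3UTR_rs50	9157	19443239
editing_ssc3utr_rs200	editing_sites	SSC_3UTR_rs200	1293	1550212	nonSSC_3UTR_rs200	8227	16311452
editing_ssc3utr_rs1000	editing_sites	SSC_3UTR_rs1000	618	433095	nonSSC_3UTR_rs1000	5303	9328336
des_ssc3utr_rs50	DES	SSC_3UTR_rs50	213	2274485	nonSSC_3UTR_rs50	1215	19443239
des_ssc3utr_rs200	DES	SSC_3UTR_rs200	206	1550212	nonSSC_3UTR_rs200	1152	16311452
des_ssc3utr_rs1000	DES	SSC_3UTR_rs1000	121	433095	nonSSC_3UTR_rs1000	891	9328336
editing_dswe	editing_sites	DSWE_genes	4156	14121576	SWE_genes	24256	100526979
des_dswe	DES	DSWE_genes	186	14121576	SWE_genes	1109	100526979
alu_dswe	Alu	DSWE_genes	9587	14121576	SWE_genes	65706	100526979
iralu_dswe	Alu_in_IR	DSWE_genes	7215	14121576	SWE_genes	47881	100526979
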