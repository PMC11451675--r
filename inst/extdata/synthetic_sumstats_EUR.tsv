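variant_id	chrom	pos	effect_allele	other_allele	beta	se	p_value	eaf	locus	ancestry
APOE_v1	1	1000000	A	G	0.551556	0.022678	1.17002e-130	0.583348	APOE	EUR
APOE_v2	1	1001000	A	G	1.29186	0.0313112	2.22507e-308	   0.15	APOE	EUR
APOE_v3	1	1002000	G	A	-0.583527	0.0234912	3.29699e-136	0.346757	APOE	EUR
APOE_v4	1	1003000	A	G	0.350487	0.0241639	1.13294e-47	0.310476	APOE	EUR
PICALM_v1	2	1000000	A	G	-0.196417	0.0230934	1.81094e-17	0.62225	PICALM	EUR
BIN1_v1	3	1000000	G	A	-0.19689	0.0228218	6.28224e-18	    0.6	BIN1	EUR
BIN1_v2	3	1001000	A	G	0.126403	0.0232131	5.17152e-08	0.634253	BIN1	EUR
BIN1_v3	3	1002000	G	A	-0.0403333	0.0229553	0.0789116	0.613067	BIN1	EUR
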