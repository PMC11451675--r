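variant_id	chrom	pos	effect_allele	other_allele	beta	se	p_value	eaf	locus	ancestry
APOE_v1	1	1000000	G	A	-0.572548	0.0365949	3.56124e-55	0.854325	APOE	AFR
APOE_v2	1	1001000	G	A	-0.829712	0.0311649	3.64884e-156	   0.78	APOE	AFR
APOE_v3	1	1002000	A	G	0.437262	0.0306945	4.77506e-46	0.770371	APOE	AFR
APOE_v4	1	1003000	G	A	-0.294292	0.0309468	1.91405e-21	0.224368	APOE	AFR
PICALM_v1	2	1000000	A	G	-0.168104	0.0258947	8.48021e-11	0.531583	PICALM	AFR
BIN1_v1	3	1000000	A	G	0.128229	0.0281718	5.32174e-06	    0.3	BIN1	AFR
BIN1_v2	3	1001000	A	G	0.0604869	0.0327737	0.0649515	0.192049	BIN1	AFR
BIN1_v3	3	1002000	A	G	0.0172097	0.0283175	0.54336	0.705316	BIN1	AFR
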