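variant_id	chrom	pos	effect_allele	other_allele	beta	se	p_value	eaf	locus	ancestry
APOE_v1	1	1000000	A	G	0.358577	0.0422012	1.94808e-17	0.831096	APOE	AMR
APOE_v2	1	1001000	A	G	0.722904	0.0486562	6.22977e-50	   0.12	APOE	AMR
APOE_v3	1	1002000	A	G	0.424698	0.0432185	8.63478e-23	0.159184	APOE	AMR
APOE_v4	1	1003000	A	G	0.187443	0.0380968	8.64625e-07	0.778834	APOE	AMR
PICALM_v1	2	1000000	A	G	-0.127313	0.0319254	6.66776e-05	0.56675	PICALM	AMR
BIN1_v1	3	1000000	G	A	-0.170907	0.0331497	2.52815e-07	   0.65	BIN1	AMR
BIN1_v2	3	1001000	A	G	0.17146	0.0378078	5.75895e-06	0.774053	BIN1	AMR
BIN1_v3	3	1002000	A	G	0.0637336	0.0373277	0.0877466	0.234336	BIN1	AMR
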