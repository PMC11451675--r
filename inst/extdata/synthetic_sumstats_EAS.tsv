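variant_id	chrom	pos	effect_allele	other_allele	beta	se	p_value	eaf	locus	ancestry
APOE_v1	1	1000000	A	G	0.545602	0.026247	5.64809e-96	0.589832	APOE	EAS
APOE_v2	1	1001000	G	A	-1.44979	0.0430331	8.08255e-249	    0.9	APOE	EAS
APOE_v3	1	1002000	A	G	0.589303	0.0293228	7.82254e-90	0.736986	APOE	EAS
APOE_v4	1	1003000	G	A	-0.31191	0.0258251	1.38354e-33	0.489993	APOE	EAS
PICALM_v1	2	1000000	G	A	0.195211	0.0261709	8.7132e-14	0.422292	PICALM	EAS
BIN1_v1	3	1000000	A	G	0.249984	0.02595	5.78413e-22	   0.45	BIN1	EAS
BIN1_v2	3	1001000	A	G	0.17681	0.0352758	5.38027e-07	0.159317	BIN1	EAS
BIN1_v3	3	1002000	A	G	0.0857486	0.0264643	0.00119464	0.609671	BIN1	EAS
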