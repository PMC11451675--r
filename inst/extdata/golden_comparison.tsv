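locus	ancestry	par	rank
APOE	AFR	0.221417	1
PICALM	AFR	0.0789762	2
BIN1	AFR	0.0394258	3
APOE	AMR	0.112885	1
BIN1	AMR	0.0612384	2
PICALM	AMR	0.0555555	3
APOE	EAS	0.245978	1
BIN1	EAS	0.11332	2
PICALM	EAS	0.0834369	3
APOE	EUR	0.283633	1
BIN1	EUR	0.0800741	2
PICALM	EUR	0.0757725	3
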