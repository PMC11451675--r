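locus	ancestry	causal_variant	true_or	true_raf	true_par
APOE	EUR	APOE_v2	    3.2	   0.15	0.24812
PICALM	EUR	PICALM_v1	   0.85	   0.64	0.0597345
BIN1	EUR	BIN1_v1	    1.2	    0.4	0.0740741
APOE	AFR	APOE_v2	    2.1	   0.22	0.194847
PICALM	AFR	PICALM_v1	   0.87	   0.55	0.0630048
BIN1	AFR	BIN1_v1	   1.15	    0.3	0.0430622
APOE	EAS	APOE_v2	    3.6	    0.1	0.206349
PICALM	EAS	PICALM_v1	   0.84	    0.6	0.0707965
BIN1	EAS	BIN1_v1	   1.25	   0.45	0.101124
APOE	AMR	APOE_v2	    1.9	   0.12	0.0974729
PICALM	AMR	PICALM_v1	   0.88	   0.58	0.0541702
BIN1	AMR	BIN1_v1	   1.18	   0.35	0.0592662
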