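dam_id	dam_karyomorph	sire_karyomorph	n_dams	n_sons	n_daughters	k_KII	k_KIII	k_KIV
KII_pooled	KII	KI	17	54	95	9	25	3
KIII_pooled	KIII	KI	18	70	101	21	6	0
KIV_pooled	KIV	KI	3	7	0	0	0	0
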