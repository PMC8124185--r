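gene_id	category	transcript_fc	protein_fc
PERK	ER proteins	16.6	4.99
Sil1	ER proteins	8.58	1.8
AsnS	ER proteins	4.3	2.3
Ire1	ER proteins	2.09	1.71
Dgp-1	Translation	21.2	2.3
CG2017	Translation	2.6	1.69
Cyp6a17	Detoxification	117	19.03
Cyp9b2	Detoxification	6.96	2.28
Cyp4e3	Detoxification	3.22	2.97
Cyp4ad1	Detoxification	1.61	1.72
Ugt37A3	Detoxification	69.4	13.27
Ugt86Dd	Detoxification	3.48	3.34
GstD2	Detoxification	7.49	3.68
GstE8	Detoxification	2.7	2.08
Hsp22	Mitochondrial proteins	29.2	28.25
Pepck2	Mitochondrial proteins	2.63	1.65
CG34423	Mitochondrial proteins	2.4	1.96
Lectin-galC1	Immunity-related proteins	3.26	9.71
BomBc3	Immunity-related proteins	2.56	3.92
CG11911	Other	6.96	9.32
Uro	Other	3.73	1.79
Ccp84Ab	Other	1.92	1.77
CG17752	Other	1.8	1.73
CG7632	Other	3.57	1.95
CG43402	Other	6.77	2.2
CG12868	Other	2.17	2.36
CG31808	Other	1.84	2.62
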