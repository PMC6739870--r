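taxon	H	Q	W	H_Q	H_W	Q_W
Prevotella melaninogenica	2.81	1.55	1.37	1.82	2.05	1.12
Clostridium perfringens	1.18	0.49	1.14	2.41	1.04	0.43
Salmonella enterica	1.77	2.29	0.79	0.77	2.25	2.90
Clostridium difficile	0.11	0.09	0.22	1.24	0.49	0.40
Lactobacillus plantarum	0.02	0.77	0.35	0.02	0.05	2.18
Vibrio cholerae	2.10	1.16	0.89	1.81	2.37	1.31
Clostridium saccharolyticum	1.21	1.44	0.59	0.84	2.05	2.45
Yersinia pseudotuberculosis	1.46	1.35	0.66	1.08	2.21	2.05
Blautia hansenii	0.54	0.74	1.80	0.72	0.30	0.41
Fusobacterium nucleatum	46.29	4.98	16.51	9.30	2.80	0.30
Contaminant	NA	NA	NA	0.89	2.13	2.38
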