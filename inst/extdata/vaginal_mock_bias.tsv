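taxon	cells	dna	pcr_product	extraction	pcr	seq_inf
Lactobacillus iners	4.7	2.3	1.2	2.0	1.9	1.2
Sneathia amnii	4.6	2.4	1.3	1.9	1.8	1.3
Lactobacillus crispatus	2.3	0.5	0.9	4.3	0.6	0.9
Prevotella bivia	1.8	0.4	0.9	4.6	0.4	0.9
Atopobium vaginae	0.3	1.1	1.0	0.3	1.0	1.0
Streptococcus agalactiae	0.2	2.0	0.9	0.1	2.2	0.9
Gardnerella vaginalis	0.2	0.4	0.8	0.4	0.5	0.8
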