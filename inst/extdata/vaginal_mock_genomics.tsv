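taxon	genome_size_mbp	copy_number
Atopobium vaginae	1.44	2
Gardnerella vaginalis	1.64	2
Lactobacillus crispatus	2.04	4
Lactobacillus iners	1.28	5
Prevotella bivia	2.52	4
Sneathia amnii	1.33	3
Streptococcus agalactiae	2.16	7
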