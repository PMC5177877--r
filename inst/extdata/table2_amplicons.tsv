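marker_id	amplicon_size	dye	primer_conc_uM
5	128	HEX	5
7	176	HEX	0.8
9	147	HEX	0.8
13	251	HEX	4
17	192	HEX	8
24	160	TAMRA	6
29	228	FAM	1.5
30	247	FAM	3
31	250	ROX	4
38	244	TAMRA	8
46	101	FAM	1
52	239	HEX	4
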