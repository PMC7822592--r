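neutral_mass_da	mass_range_high_da	relative_abundance_pct	label	reported_modification	reported_oligosaccharide
5855.6676	NA	0.54	t3_r1	Glycosylation + 2x Gla	HexNAc, Hex, NANA
5899.7161	NA	7.43	t3_r2	Glycosylation + 3x Gla	HexNAc, Hex, NANA
5915.6386	6135.6796	36.07	t3_r3	Glycosylation + 3x Gla + oxidation + additional unidentified modifications or adduct ions	HexNAc, Hex, NANA
6146.7609	6162.7991	5.42	t3_r4	Glycosylation + 2x Gla + additional unidentified modifications	HexNAc, Hex, 2x NANA
6190.8061	NA	4.49	t3_r5	Glycosylation + 3x Gla	HexNAc, Hex, 2x NANA
6206.8016	6441.7636	45.12	t3_r6	Glycosylation + 3x Gla + oxidation + additional unidentified modifications or adduct ions	HexNAc, Hex, 2x NANA
5259.4204	NA	0.93	t3_r7	3x Gla + oxidation	NA
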