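neutral_mass_da	mass_range_high_da	relative_abundance_pct	label	reported_modification	reported_oligosaccharide
5767.6961	NA	4.80	t2_r01	Glycosylation	HexNAc, Hex, NANA
5783.6801	NA	0.25	t2_r02	Glycosylation + oxidation	HexNAc, Hex, NANA
5855.6676	NA	4.60	t2_r03	Glycosylation + 2x Gla	HexNAc, Hex, NANA
5899.7161	NA	3.16	t2_r04	Glycosylation + 3x Gla	HexNAc, Hex, NANA
5915.6386	5968.5796	5.51	t2_r05	Glycosylation + 3x Gla + oxidation + additional unidentified modifications or adduct ions	HexNAc, Hex, NANA
6058.7916	NA	24.48	t2_r06	Glycosylation	HexNAc, Hex, 2x NANA
6074.7766	6096.7409	2.48	t2_r07	Glycosylation + oxidation	HexNAc, Hex, 2x NANA
6102.7681	NA	7.89	t2_r08	Glycosylation + 1x Gla	HexNAc, Hex, 2x NANA
6146.7609	NA	23.97	t2_r09	Glycosylation + 2x Gla	HexNAc, Hex, 2x NANA
6190.8061	6214.7278	6.72	t2_r10	Glycosylation + 3x Gla + additional unidentified modifications or adduct ions	HexNAc, Hex, 2x NANA
5127.4676	NA	3.00	t2_r11	Oxidation	NA
5171.4301	NA	1.85	t2_r12	1x Gla + oxidation	NA
5199.4446	NA	2.08	t2_r13	2x Gla	NA
5215.4296	NA	8.50	t2_r14	2x Gla + oxidation	NA
5259.4204	NA	0.66	t2_r15	3x Gla + oxidation	NA
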