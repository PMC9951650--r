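trait	sigma2_g1	sigma2_g2	cov_g12	rg_printed
milk_yield	470936.770	102.627	5005.297	0.720
fat_yield	634.546	94.554	175.126	0.715
protein_yield	422.192	95.1678	124.551	0.621
body_conformation	29.540	102.790	12.190	0.221
feet_legs	40.368	109.742	9.601	0.144
mammary_system	31.657	123.003	14.707	0.236
somatic_cell_score	58.536	101.069	34.502	0.449
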