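lambda	rep	dG_dlambda_kcal_mol
0	1	-32.9
0	2	-34.7
1	1	-54.9
1	2	-57.1
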