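lambda	dG_dlambda_kcal_mol
0	-24.6
0.25	-51.0
0.5	-81.1
0.75	-104.9
1	-129.1
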