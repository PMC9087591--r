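run_id	method	total_kcal_mol
solution	BAR	-80.5
A	BAR	-79.1
A'	BAR	-87.0
B	BAR	-74.5
B'	BAR	-74.6
C	BAR	-70.1
C'	BAR	-74.3
solution	TI	-80.4
A	TI	-79.4
A'	TI	-87.1
B	TI	-74.6
B'	TI	-75.1
C	TI	-70.5
C'	TI	-74.7
mean	TI	-78.3
mean_corrected	TI	-81.2
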