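run_id	lambda_from	lambda_to	dG_kcal_mol
solution	0	0.25	-8.5
solution	0.25	0.5	-16.3
solution	0.5	0.75	-23.6
solution	0.75	1	-32.1
A	0	0.25	-10.7
A	0.25	0.5	-16.9
A	0.5	0.75	-23.5
A	0.75	1	-28.1
A'	0	0.25	-14.2
A'	0.25	0.5	-20.5
A'	0.5	0.75	-24.0
A'	0.75	1	-28.1
B	0	0.25	-8.9
B	0.25	0.5	-15.7
B	0.5	0.75	-21.4
B	0.75	1	-28.4
B'	0	0.25	-8.9
B'	0.25	0.5	-15.8
B'	0.5	0.75	-21.4
B'	0.75	1	-28.5
C	0	0.25	-7.8
C	0.25	0.5	-15.0
C	0.5	0.75	-20.5
C	0.75	1	-26.7
C'	0	0.25	-10.1
C'	0.25	0.5	-16.1
C'	0.5	0.75	-21.2
C'	0.75	1	-26.9
d	0.5	0.75	-23.9
d	0.75	1	-28.5
d'	0.5	0.75	-25.0
d'	0.75	1	-29.1
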