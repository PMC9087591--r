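run_id	lambda	dG_dlambda_kcal_mol	weight_ns
solution	0	-18.0	20
solution	0.25	-50.3	20
solution	0.5	-79.4	20
solution	0.75	-109.8	20
solution	1	-147.5	20
A	0	-30.5	40
A	0.25	-54.7	40
A	0.5	-85.8	40
A	0.75	-100.7	40
A	1	-129.6	40
A'	0	-39.8	40
A'	0.25	-71.6	40
A'	0.5	-91.3	40
A'	0.75	-101.3	40
A'	1	-130.5	40
B	0	-22.3	40
B	0.25	-49.3	40
B	0.5	-74.6	40
B	0.75	-98.5	40
B	1	-132.2	40
B'	0	-23.3	40
B'	0.25	-50.4	40
B'	0.5	-73.6	40
B'	0.75	-99.4	40
B'	1	-131.6	40
C	0	-18.7	40
C	0.25	-46.9	40
C	0.5	-70.5	40
C	0.75	-94.5	40
C	1	-120.4	40
C'	0	-28.5	40
C'	0.25	-53.7	40
C'	0.5	-73.8	40
C'	0.75	-96.1	40
C'	1	-120.7	40
d	0.5	-87.9	80
d	0.75	-104.4	80
d	1	-127.6	80
d'	0.5	-90.2	80
d'	0.75	-109.3	80
d'	1	-129.5	80
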