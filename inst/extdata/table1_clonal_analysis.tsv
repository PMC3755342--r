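region1	region2	clones	boundary_clones	crossed_clones	total_cells	boundary_cells	crossed_cells	p_annotation	note
A1	A2	52	2	0	21	10	0	p<0.05
A2	A1	250	4	0	34	12	0	p<0.01
A3	Cu	86	3	0	29	14	0	p<0.01
Cu	A3	0	0	0	0	0	0	n.a.
Cu	LFC	94	3	0	16	7	0	p<0.05
LFC	Cu	24	1	0	8	3	0	n.s.
LFC	Fe	67	7	7	52	37	23
Fe	LFC	235	10	8	63	36	25
Fe	P1	172	4	0	26	12	0	p<0.01
P1	Fe	833	3	0	24	9	0	p<0.01
P1	P2	560	7	0	62	28	0	p<0.01
P2	P1	952	5	0	45	25	0	p<0.01	2 dying
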