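stage	trait	p1_mean	p1_sd	f1_mean	f1_sd	p2_mean	p2_sd	mph_printed	hph_printed
tillering	Root length (cm)	31.96	3.21	33.34	1.77	25.58	2.63	15.88	4.32
tillering	Root dry weight (g)	1.45	0.04	3.11	0.13	2.24	0.01	68.56	38.84
tillering	Root-shoot ratio	0.20	0.02	0.25	0.00	0.19	0.01	28.21	25.00
tillering	Shoot dry weight (g)	7.45	0.81	12.48	0.39	12.07	0.85	27.85	3.36
heading	Root length (cm)	48.63	2.73	64.45	3.07	37.50	2.45	49.66	32.53
heading	Root dry weight (g)	6.44	0.52	11.27	0.34	3.06	0.22	137.26	75.00
heading	Root-shoot ratio	0.15	0.00	0.18	0.02	0.13	0.00	28.57	20.00
heading	Shoot dry weight (g)	43.21	1.34	61.86	0.64	24.13	5.15	92.29	43.16
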