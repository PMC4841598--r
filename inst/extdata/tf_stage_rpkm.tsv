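gene_id	family	module	MT170	MT190	MT210	WT170	WT190	WT210
Cs1g06760	NAC	yellow	41.70	100.33	290.49	97.95	130.30	301.33
Cs2g02790	WRKY	yellow	3.05	9.34	26.03	6.56	11.66	25.68
Cs3g23950	MYB	yellow	13.82	14.06	0.81	13.23	3.34	NA
Cs1g23790	GRAS	turquoise	9.43	2.54	1.95	8.70	6.11	0.82
Cs5g26470	GATA	turquoise	33.37	7.76	2.76	14.32	3.73	1.34
Cs7g01850	C2H2	turquoise	25.55	10.73	4.68	17.24	5.25	2.77
Cs7g03670	Dof	red	12.55	6.24	7.28	5.94	8.32	3.69
Cs2g27940	MYB_related	red	NA	1.02	7.00	0.07	7.32	31.64
Cs3g19420	ERF	midnightblue	43.47	40.92	8.62	20.97	21.59	3.06
Cs2g12700	MYB	green	0.80	4.80	NA	4.25	3.69	NA
Cs4g13650	HRT-like	brown	15.29	4.39	1.64	12.92	10.37	2.56
Cs5g01740	Dof	brown	12.95	6.02	2.66	13.67	12.64	4.72
Cs5g26420	G2-like	brown	4.56	1.56	NA	4.41	5.61	0.42
Cs8g18320	Dof	brown	4.41	1.07	NA	5.50	4.71	1.31
Cs8g04300	LBD	blue	5.88	0.96	2.40	14.86	3.04	1.79
Cs7g26710	LBD	blue	8.10	2.67	0.68	36.38	2.73	2.17
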