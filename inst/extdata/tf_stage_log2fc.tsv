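gene_id	fc170	fc190	fc210
Cs1g06760	-1.23	-0.38	-0.05
Cs2g02790	-1.11	-0.32	0.02
Cs3g23950	0.06	2.07	9.66
Cs1g23790	0.12	-1.27	1.26
Cs5g26470	1.22	1.06	1.04
Cs7g01850	0.57	1.03	0.75
Cs7g03670	1.08	-0.42	0.98
Cs2g27940	-6.21	-2.84	-2.18
Cs3g19420	1.05	0.92	1.50
Cs2g12700	-2.41	0.38	0.00
Cs4g13650	0.24	-1.24	-0.64
Cs5g01740	-0.08	-1.07	-0.83
Cs5g26420	0.05	-1.84	-8.70
Cs8g18320	-0.32	-2.13	-10.36
Cs8g04300	-1.34	-1.66	0.42
Cs7g26710	-2.17	-0.03	-1.66
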