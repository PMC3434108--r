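id	taxon	species	source	superposed_pct	rmsd	d_asp_his	d_his_ser	d_asp_ser
1ARC-A	Bacteria	A. lyticus	experimental	10.6	0.932	6.4	8.2	9.7
1QY6-A	Bacteria	S. aureus	experimental	16.2	0.753	7.1	8.4	9.9
1SGC-A	Bacteria	S. griseus	experimental	19.3	0.744	6.2	8.5	9.8
1TRY-A	Fungi	F. oxysporum	experimental	41.6	0.493	6.2	8.4	10.1
1EKB-B	Animalia	B. taurus	experimental	41.3	0.744	6.4	8.0	9.3
1JRS-A	Animalia	B. taurus	experimental	45.3	0.642	6.5	8.4	10.3
1M9U-A	Animalia	E. fetida	experimental	41.9	0.768	6.5	8.5	10.2
1SGI-B	Animalia	H. sapiens	experimental	100	0.000	6.4	8.4	10.3
1A0L-A	Animalia	H. sapiens	experimental	42.3	0.552	6.4	8.3	10.3
1ABJ-H	Animalia	H. sapiens	experimental	100	0.424	6.6	8.1	9.3
2ANY-A	Animalia	H. sapiens	experimental	42.4	0.541	6.3	8.3	9.8
1AO5-A	Animalia	M. musculus	experimental	44.1	0.552	6.6	8.2	9.7
1DPO-A	Animalia	R. rattus	experimental	45.5	0.652	6.3	7.6	9.8
1BIT-A	Animalia	S. salar	experimental	46.4	0.610	6.3	9.9	9.9
1EQ9-A	Animalia	S. invicta	experimental	44.6	0.593	6.3	8.1	10.1
1BQY-A	Animalia	T. stejnejer	experimental	41.5	0.645	6.4	8.3	9.7
PM0075793	Protozoa	P. falciparum	predicted	15.0	1.003	6.2	8.4	9.9
PM0075794	Archaea	P. furiosus	predicted	22.5	0.756	6.5	8.3	9.7
PM0075795	Fungi	N. crassa	predicted	13.0	1.311	6.4	9.4	10.8
PM0075796	Plantae	A. thaliana	predicted	16.4	1.761	6.7	9.6	10.1
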