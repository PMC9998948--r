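te_class	order	superfamily	category	pct_genome_incl	pct_genome_excl	contigs_100	contigs_95	contigs_80	mean_contig_bp	longest_contig_bp	transcriptome_contigs	tpm_ovary	tpm_testis
I	LTR	Gypsy	superfamily	3.85	6.50	5985	5464	3835	548	7587	2057	827	3024
I	LTR	ERV	superfamily	0.41	0.43	413	394	264	593	11567	321	392	694
I	LTR	Copia	superfamily	0.10	0.25	23	21	19	592	1353	27	31	26
I	LTR	Bel-Pao	superfamily	0.05	0.05	12	7	2	575	766	NA	NA	NA
I	LTR	Retrovirus	superfamily	NA	NA	3	2	2	1375	1719	10	1	10
I	LTR	THE1	superfamily	NA	NA	4	4	3	491	674	NA	NA	NA
I	LTR	unknown	unknown	NA	NA	4	4	4	469	955	NA	NA	NA
I	DIRS	DIRS	superfamily	4.44	5.95	8087	7821	3844	379	4266	4844	5427	11962
I	PLE	Penelope	superfamily	0.09	0.12	482	462	376	407	3208	460	123	352
I	LINE	Jockey	superfamily	9.69	12.12	25276	23361	13287	426	3625	11622	6206	15535
I	LINE	L1	superfamily	5.04	6.62	10189	8997	5941	672	6546	8241	2954	7610
I	LINE	RTE	superfamily	0.12	0.24	227	201	137	676	4540	399	130	360
I	LINE	I	superfamily	0.09	0.17	32	25	10	905	3858	48	42	125
I	LINE	R2	superfamily	NA	NA	NA	NA	NA	NA	NA	1	NA	1
I	LINE	unknown	unknown	0.39	1.89	90	77	72	1393	5881	1	NA	NA
I	SINE	5S	superfamily	0.23	0.18	57	41	15	773	1783	4	5	1
I	SINE	7SL	superfamily	NA	NA	43	41	15	243	450	2	1	NA
I	SINE	tRNA	superfamily	NA	NA	22	22	22	273	403	NA	NA	NA
I	SINE	unknown	unknown	0.45	3.42	365	348	338	377	695	219	2901	2471
I	derivative	TRIM	derivative	3.80	9.76	748	631	465	588	2619	492	1651	5847
I	derivative	LARD	derivative	0.15	0.73	45	37	35	2834	8148	153	515	2643
II	TIR	PIF-Harbinger	superfamily	2.98	4.22	1164	1014	434	411	5169	416	575	1359
II	TIR	hAT	superfamily	1.15	1.12	177	135	55	869	5706	35	83	26
II	TIR	Tc1-Mariner	superfamily	0.18	0.63	73	40	24	1025	3781	20	58	87
II	TIR	PiggyBac	superfamily	0.05	0.08	9	8	6	1087	1956	6	21	15
II	TIR	MuDR	superfamily	NA	NA	3	3	3	266	417	13	4	10
II	TIR	CACTA	superfamily	NA	NA	2	2	2	645	846	3	2	1
II	TIR	ISL2EU	superfamily	NA	NA	NA	NA	NA	NA	NA	1	18	16
II	TIR	Ginger	superfamily	NA	NA	NA	NA	NA	NA	NA	4	10	6
II	TIR	Academ	superfamily	NA	NA	NA	NA	NA	NA	NA	11	5	8
II	TIR	P	superfamily	NA	NA	NA	NA	NA	NA	NA	1	1	1
II	TIR	unknown	unknown	0.33	1.46	22	20	19	754	2174	NA	NA	NA
II	derivative	MITE	derivative	0.56	4.07	357	346	321	258	1942	137	465	1188
II	Maverick	Maverick	superfamily	0.05	0.05	258	228	65	583	6090	123	44	762
II	Helitron	Helitron	superfamily	0.18	0.48	49	38	19	939	6551	13	2	10
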