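family	superfamily	intact_copies	A_hits	A_loci	B_hits	B_loci	C_hits	C_loci	D_hits	D_loci	E_hits	E_loci	additional_loci
Gmr1	Gypsy	564	121	15	67	14	70	15	28	15	49	16	16
Gmr2	Copia	837	24	5	34	5	37	5	8	4	17	6	4
Gmr3	Gypsy	867	88	12	72	10	87	13	15	8	33	12	28
Gmr4	Gypsy	1363	354	38	224	37	226	38	90	38	150	50	78
Gmr5	Copia	401	141	20	73	13	75	14	28	14	50	18	42
Gmr6	Copia	763	203	19	115	18	141	23	41	18	68	20	12
Gmr7	Copia	195	10	1	4	1	6	2	3	2	6	3	1
Gmr9	Gypsy	3247	13293	1561	9137	1428	9211	1543	2999	1468	5510	1890	3975
Gmr12	Gypsy	114	44	5	34	5	42	5	10	3	20	6	2
Gmr14	Copia	43	0	0	0	0	1	1	0	0	0	0	0
Gmr15	Copia	84	4	1	4	1	1	1	1	1	2	1	0
Gmr16	Copia	116	6	1	0	0	0	0	0	0	0	0	0
Gmr17	Gypsy	422	23	3	16	2	2	2	2	2	4	2	1
Gmr18	Copia	204	10	2	14	2	16	2	5	2	8	3	1
Gmr19	Gypsy	581	214	27	113	24	114	22	46	20	76	28	19
Gmr21	Gypsy	157	85	12	89	14	76	13	34	15	59	18	6
Gmr22	Copia	119	3	1	4	1	1	1	1	1	2	1	0
Gmr24	Copia	79	2	1	5	1	4	1	0	0	2	1	0
Gmr25	Gypsy	307	111	13	61	11	71	13	28	10	48	13	21
Gmr28	Copia	100	7	1	14	1	15	1	2	1	4	1	0
Gmr34	Gypsy	120	2	1	4	1	1	1	1	1	2	1	9
Gmr35	Copia	95	9	1	8	1	11	2	2	1	4	1	0
Gmr37	Copia	255	35	4	50	5	51	5	9	4	22	10	5
Gmr51	Gypsy	27	4	1	0	0	0	0	1	1	3	2	0
Gmr52	Gypsy	20	6	1	0	0	0	0	0	0	0	0	0
Gmr59	Gypsy	31	0	0	0	0	3	1	0	0	0	0	0
Gmr68	Copia	12	13	1	6	1	7	1	3	1	6	2	0
Gmr75	Gypsy	17	9	2	6	2	5	2	4	2	6	2	0
Gmr79	Gypsy	49	3	1	0	0	2	1	0	0	0	0	0
Gmr80	Gypsy	6	12	1	5	1	7	1	2	1	4	1	0
Gmr90	Copia	10	9	1	4	1	5	1	4	1	5	1	0
Gmr110	Gypsy	6	0	0	0	0	2	1	0	0	0	0	0
Gmr123	Gypsy	3	0	0	0	0	1	1	0	0	0	0	0
Gmr128	Gypsy	5	10	2	7	2	9	2	5	2	8	2	0
Gmr139	Gypsy	88	28	4	26	4	14	4	5	4	11	4	12
Gmr146	Gypsy	3	0	0	0	0	0	0	0	0	1	1	0
Gmr163	Gypsy	3	1	1	5	1	6	1	2	1	4	1	0
Gmr169	Gypsy	18	12	1	5	1	8	2	4	3	10	4	4
Gmr190	Copia	21	12	1	5	1	7	1	3	2	7	2	0
Gmr192	Gypsy	3	0	0	0	0	0	0	0	0	1	1	0
Gmr290	Gypsy	3	1	1	0	0	0	0	1	1	0	0	0
Gmr459	Gypsy	10	0	0	0	0	0	0	0	0	1	1	0
Gmr522	Gypsy	17	6	1	6	1	0	0	1	1	2	1	0
Others	Multi	ND	ND	ND	ND	ND	ND	ND	ND	ND	ND	ND	17
Unknown	NA	ND	ND	ND	ND	ND	ND	ND	ND	ND	ND	ND	75
Total	ND	11385	14915	1763	10217	1610	10335	1742	3388	1648	6205	2126	4328
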