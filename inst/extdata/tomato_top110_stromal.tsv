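rank	protein_id	protein_name	mol_percent
1	544163620	ATPB	13.886
2	544163621	RBCL	10.412
3	544163653	RPS19	6.442
4	Solyc06g073260	CSP41B	4.477
5	544163671	RPS15	4.062
6	Solyc06g007760	YCF54	4.062
7	Solyc01g087040	TL19	2.033
8	Solyc10g076350	NA	2.033
9	Solyc08g074630	PPO-F	1.948
10	Solyc08g074620	PPO-E	1.507
11	Solyc06g071790	EF-TuB	1.335
12	Solyc10g086150	CP29B	1.202
13	Solyc10g086580	RCA2A	1.169
14	Solyc09g007850	CP29A	1.069
15	Solyc03g095180	Fe-SOD2	1.016
16	544163678	RPL23	0.940
17	Solyc02g083500	AANH-like	0.853
18	Solyc03g112150	EF-TuA	0.797
19	Solyc09g065180	CSP41A	0.738
20	Solyc09g011080	RCA2B	0.710
21	544163619	ATPE	0.638
22	Solyc02g079950	OEE3	0.638
23	Solyc02g086740	RPL12-A	0.638
24	544163598	ATPA	0.506
25	Solyc04g007010	KIROLA-like	0.433
26	Solyc12g056830	ATPD	0.433
27	Solyc12g042060	CLPC1	0.408
28	Solyc01g080280	GS2	0.400
29	Solyc02g086730	RPL12-C	0.400
30	Solyc12g013810	TRX-m4.1	0.400
31	Solyc01g057830	RPS1A	0.393
32	Solyc01g106430	PPA6	0.387
33	Solyc01g103450	HSC70-2	0.375
34	Solyc07g066610	cpPGK1	0.343
35	Solyc07g062060	MSRB1	0.328
36	Solyc02g020940	GAPA-2	0.317
37	Solyc02g086820	CA1	0.317
38	Solyc08g006070	AIG2-like	0.293
39	Solyc10g018300	TKL1	0.293
40	Solyc03g118240	CHLM	0.280
41	Solyc02g083810	LFRN PETH	0.275
42	Solyc02g084440	FBA3	0.270
43	Solyc08g076220	PRK	0.265
44	544163637	CLPP1	0.250
45	Solyc02g080540	ATPC	0.250
46	Solyc04g009030	GAPA-1	0.250
47	Solyc11g066390	SOD3	0.250
48	Solyc07g056540	GLO1	0.238
49	Solyc07g044860	OEE2	0.229
50	Solyc11g069790	CPN60A2	0.228
51	Solyc04g074750	CP33C	0.225
52	Solyc12g010840	NA	0.222
53	Solyc01g097460	RPI3	0.216
54	544163595	RPS16	0.197
55	Solyc01g009990	CYP20-2	0.197
56	Solyc04g008710	NA	0.197
57	Solyc05g005480	NA	0.197
58	Solyc05g009030	IMDH	0.197
59	Solyc05g052710	RPS31	0.197
60	Solyc08g006780	STIC2-like	0.197
61	Solyc08g081570	MeCPS	0.197
62	Solyc08g079180	EF-G	0.179
63	Solyc01g100520	CLPP5	0.177
64	Solyc03g121910	TS1	0.177
65	Solyc01g108600	PREP1	0.174
66	Solyc03g007110	CLPT1	0.173
67	Solyc06g048410	Fe-SOD2 (PAP9)	0.167
68	Solyc03g118340	CLPC2	0.151
69	Solyc12g010380	AK5	0.151
70	Solyc06g048730	UROD2	0.146
71	Solyc05g005880	RPS13	0.143
72	Solyc01g079790	APL1	0.140
73	Solyc03g063560	GLU1	0.134
74	Solyc01g009080	NA	0.132
75	Solyc01g111120	pdTPI-2A	0.132
76	Solyc05g052600	SBPase	0.132
77	Solyc07g025520	NA	0.132
78	Solyc07g053280	NA	0.132
79	Solyc07g063190	Trx-m4.3	0.132
80	Solyc11g006020	NDHO	0.132
81	Solyc12g094640	GAPB	0.132
82	Solyc02g086910	CYP38	0.127
83	Solyc04g009200	GSA	0.127
84	Solyc01g028810	CPN60B2	0.127
85	Solyc01g110360	FBA1	0.122
86	Solyc02g085100	NA	0.122
87	Solyc03g111840	NA	0.122
88	Solyc03g120430	GLYK	0.122
89	Solyc04g082630	GAPB	0.121
90	Solyc06g053600	At1g04420-like1	0.120
91	Solyc01g006980	MCAT	0.118
92	Solyc01g108630	NIR	0.118
93	Solyc03g120850	CPN60B1	0.118
94	Solyc06g076790	NA	0.118
95	Solyc09g008670	OMR1A	0.116
96	Solyc02g062340	FBA2	0.116
97	544163615	RPS4	0.114
98	Solyc02g088610	CLPB3	0.111
99	Solyc01g105060	NA	0.108
100	Solyc10g054870	pdTPI-2B	0.108
101	Solyc12g010020	LapA1	0.108
102	Solyc12g089210	OTC2	0.108
103	Solyc12g094430	GSTF5	0.108
104	Solyc01g005520	MET1	0.105
105	Solyc01g006560	LOXF	0.105
106	Solyc03g111610	NA	0.104
107	Solyc02g065400	PSBO-1	0.101
108	Solyc04g007790	KIROLA-like	0.101
109	Solyc04g015040	FKBP16-3	0.101
110	Solyc06g072470	RPL29	0.101
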