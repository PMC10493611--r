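functional_class	protein_id	protein_name	arabidopsis_homolog	peptides	psms	empai	mol_percent	n_samples_detected
Defense	Solyc08g074620	PPO-E	NA	31	853	233.62	1.5065	6
Defense	Solyc08g074680	PPO-A	NA	20	115	1.89	0.0122	5
Proteolysis	Solyc12g097030	CTPA2	At4g17740	18	76	3.76	0.0242	8
Proteolysis	Solyc02g071190	CTPA1	At5g46390	14	48	5.06	0.0326	8
Proteolysis	Solyc03g059260	CTPA3	At3g57680	2	4	0.39	0.0025	4
Proteolysis	Solyc02g086830	DEG1	At3g27925	13	137	11.92	0.0768	8
Proteolysis	Solyc08g048550	DEG5	At4g18370	4	29	2.42	0.0156	8
Proteolysis	Solyc02g067360	DEG8	At5g39830	9	30	3.44	0.0222	8
Protein folding	Solyc08g006540	FKBP13	At5g45680	6	38	2.83	0.0183	8
Protein folding	Solyc04g054520	FKBP16-2	At4g39710	4	7	4.18	0.0269	7
Protein folding	Solyc04g015040	FKBP16-3	At2g43560	6	93	15.68	0.1011	8
Protein folding	Solyc09g008650	FKBP16-4	At3g10060	1	1	0.21	0.0014	1
Protein folding	Solyc02g069130	FKBP17-1	At4g19830	3	8	1.68	0.0109	8
Protein folding	Solyc03g119150	FKBP17-3	At1g18170	2	2	0.67	0.0043	5
Protein folding	Solyc04g082660	FKBP18	At1g20810	3	7	0.78	0.0050	6
Protein folding	Solyc11g033284	FKBP19	At5g13410	3	19	6.20	0.0400	7
Protein folding	Solyc10g039270	FKBP20-2	At3g60370	5	13	1.15	0.0074	7
Protein folding	Solyc02g086910	CYP38	At3g01480	13	194	19.69	0.1270	8
Protein folding	Solyc01g009990	CYP20-2	At5g13120	10	191	30.62	0.1975	8
Protein folding	Solyc12g013580	CYP37	At3g15520	7	30	1.68	0.0109	8
Cytb6/f complex	Solyc12g005630	PETC	At4g03280	3	44	1.61	0.0104	8
Cytb6/f complex	Solyc04g082010	PETE	At1g20340	1	44	5.31	0.0342	8
Cytb6/f complex	Solyc02g068930	PETJ	At5g45040	2	10	0.43	0.0027	7
NAD(P)H complex	Solyc10g054420	PNSL1	At2g39470	3	7	1.15	0.0074	7
NAD(P)H complex	Solyc05g007780	PNSL2	At1g14150	1	6	0.78	0.0050	5
NAD(P)H complex	Solyc10g006530	PNSL3	At3g01440	2	4	1.51	0.0098	5
Photosystem I	Solyc08g013670	PSAN	At5g64040	1	16	0.33	0.0022	7
Photosystem II	Solyc02g065400	PSBO-2 (OEE1)	At3g50820	15	300	15.68	0.1011	8
Photosystem II	Solyc02g090030	PSBO-2 (OEE1)	At3g50820	15	309	13.13	0.0846	8
Photosystem II	Solyc07g044860	PSBP (OEE2)	At1g06680	13	484	35.52	0.2290	8
Photosystem II	Solyc02g079950	PSBQ (OEE3)	At4g05180	18	199	99.00	0.6384	8
Photosystem assembly	Solyc12g005180	LCNP	At3g47860	8	37	6.02	0.0388	8
Photosystem assembly	Solyc02g014150	HCF136	At5g23120	12	223	12.11	0.0781	8
Photosystem assembly	Solyc02g083270	LTO1 (VKOR)	At4g35760	3	5	1.15	0.0074	2
Photosystem assembly	Solyc01g106090	PPD1	At4g15510	11	68	6.08	0.0392	8
Photosystem assembly	Solyc04g009420	PPD2	At2g28605	9	29	9.00	0.0580	8
Photosystem assembly	Solyc12g094720	PPD3	At1g76450	7	92	9.00	0.0580	8
Photosystem assembly	Solyc04g064670	PPD4	At1g77090	7	46	7.11	0.0459	8
Photosystem assembly	Solyc08g067840	PPD5	At5g11450	6	23	1.89	0.0122	8
Photosystem assembly	Solyc06g065490	PPD6	At3g56650	4	68	2.51	0.0162	8
Photosystem assembly	Solyc03g114930	PPL1	At3g55330	7	49	5.58	0.0360	8
Photosystem assembly	Solyc07g054290	PSB27-H1	At1g03600	3	9	1.51	0.0098	8
Photosystem assembly	Solyc09g076030	PSB27-H2	At1g05385	8	37	4.88	0.0315	8
Photosystem assembly	Solyc09g064500	PSB28	At4g28660	4	21	3.22	0.0207	6
Photosystem assembly	Solyc06g076480	TL15-1	At2g44920	4	27	1.15	0.0074	8
Photosystem assembly	Solyc10g084040	TL15-2	At5g52970	7	44	7.11	0.0459	8
Photosystem assembly	Solyc12g009600	TL16.5 (MPH2)	At4g02530	11	85	10.94	0.0705	8
Photosystem assembly	Solyc03g082890	TL17.4	At5g53490	7	39	3.92	0.0253	8
Photosystem assembly	Solyc03g019660	TL17.9	At4g24930	6	29	6.50	0.0419	7
Photosystem assembly	Solyc01g098640	TL18.3	At1g54780	10	34	5.31	0.0342	8
Photosystem assembly	Solyc01g087040	TL19	At3g63540	9	122	315.23	2.0328	8
Photosystem assembly	Solyc08g079110	TL20.3	At1g12250	9	74	6.36	0.0410	8
Photosystem assembly	Solyc04g074640	TL29	At4g09010	8	34	2.59	0.0167	8
Xanthophyll synthesis	Solyc04g051610	VDE-like	At2g21860	1	1	0.17	0.0011	1
Xanthophyll synthesis	Solyc04g050930	VDE1	At1g08550	17	98	5.58	0.0360	8
Unknown	Solyc05g012600	NA	At2g03420	1	4	0.26	0.0017	4
Unknown	Solyc09g005740	NA	At2g37400	7	30	1.68	0.0109	8
Unknown	Solyc12g019550	NA	At1g21500	2	4	2.16	0.0139	3
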