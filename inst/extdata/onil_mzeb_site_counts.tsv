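class	region	identity_pct	dxy_pct	length_on	length_mz	D	S	printed_pdiv	printed_p
CNE	CNE_1	96.84	3.23	158	158	0	2	0.0	1.000
CNE	CNE_2	96.22	3.88	240	239	2	6	25.0	0.130
CNE	CNE_3	94.74	4.53	349	359	7	1	87.5	<0.001
CNE	CNE_4	98.31	1.70	240	241	2	0	100.0	0.006
CNE	CNE_5	96.14	3.97	207	207	1	0	100.0	0.080
CNE	CNE_6	NA	NA	300	NA	NA	NA	NA	NA
CNE	CNE_7	97.16	2.89	882	885	1	8	11.1	0.528
CNE	CNE_8	88.46	4.86	779	799	3	9	25.0	0.065
CNE	CNE_9	93.93	6.33	313	313	1	3	25.0	0.283
CNE	CNE_10	97.64	2.40	127	127	0	0	NA	NA
CNE	CNE_11	95.97	4.14	124	124	1	1	50.0	0.154
CNE	CNE_12	95.53	4.61	246	249	1	3	25.0	0.284
CNE	CNE_13	97.66	2.37	214	214	1	9	10.0	0.566
CNE	CNE_14	88.97	4.71	999	1404	1	9	10.0	0.566
CNE	CNE_15	95.32	4.84	428	428	3	6	33.3	0.030
CNE	CNE_16	91.21	9.35	182	191	0	2	0.0	1.000
CNE	CNE_17	96.14	3.96	311	313	2	3	40.0	0.054
CNE	CNE_18	93.25	7.07	1087	976	5	13	27.8	0.012
CNE	CNE_19	NA	NA	69	NA	NA	NA	NA	NA
CNE	CNE_20	98.88	1.13	358	38	1	13	7.1	1.000
promoter	LWS_prom	97.56	2.48	1000	1000	1	16	5.9	1.000
promoter	RH2Aa_prom	94.80	5.38	1000	1000	10	11	47.6	<0.001
promoter	RH2Ab_prom	91.77	8.60	1000	1000	14	19	42.4	<0.001
promoter	RH2B_prom	61.35	9.40	1000	1000	15	7	68.1	<0.001
promoter	SWS1_prom	71.49	26.37	1000	1000	18	10	64.3	<0.001
promoter	SWS2A_prom	97.19	2.87	1000	1000	11	12	47.8	<0.001
promoter	SWS2B_prom	81.96	16.31	1000	1000	4	10	28.6	0.021
UTR3	LWS_utr	93.39	6.92	189	189	1	4	20.0	0.341
UTR3	RH2Aa_utr	94.04	6.21	438	442	4	9	30.8	0.016
UTR3	RH2Ab_utr	93.26	7.06	465	460	4	11	26.7	0.027
UTR3	RH2B_utr	93.15	7.18	310	319	4	4	50.0	0.002
UTR3	SWS1_utr	96.74	3.33	217	242	1	3	25.0	0.284
UTR3	SWS2A_utr	98.37	1.64	123	123	0	1	0.0	1.000
UTR3	SWS2B_utr	95.90	4.21	124	137	4	1	80.0	<0.001
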