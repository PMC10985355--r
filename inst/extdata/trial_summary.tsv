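trait	env	mean	sd	min	max	ecv	cv_a	cv_b	h2	ga	gam
DTF	WW17	183.01	5.82	168	189	2.66	3.18	4.15	58.73	7.84	4.29
DTF	DS17	186.00	6.34	171	192	1.20	3.39	3.59	88.91	10.45	5.62
DTF	WW18	180.64	3.57	171	188	0.89	1.98	2.17	83.26	5.74	3.18
DTF	DS18	180.62	4.13	166	187	0.48	2.23	2.28	95.65	6.93	3.83
DTF	WW20	183.54	9.03	171	201	0.54	4.95	4.98	98.82	15.91	8.67
DTF	DS20	184.89	9.14	172	202	0.83	4.98	5.05	97.31	16.00	8.65
DTSD	WW17	190.73	4.97	179	197	2.02	2.56	3.26	61.70	6.75	3.54
DTSD	DS17	193.04	5.81	182	190	1.15	3.01	3.22	87.19	9.54	4.94
DTSD	WW18	187.73	3.18	179	198	0.56	1.67	1.76	89.81	5.22	2.78
DTSD	DS18	186.88	3.45	173	195	0.55	1.79	1.87	91.39	5.62	3.01
DTSD	WW20	192.47	10.02	179	213	0.92	5.22	5.30	96.97	17.40	9.04
DTSD	DS20	193.72	9.71	181	212	0.95	5.01	5.10	96.52	16.77	8.66
DTR	WW17	256.84	2.27	253	273	0.79	0.87	1.17	54.99	2.91	1.13
DTR	DS17	255.31	2.15	252	262	0.56	0.84	1.01	69.02	3.12	1.22
DTR	WW18	268.80	1.46	266	274	0.42	0.54	0.68	62.46	2.01	0.75
DTR	DS18	267.80	1.28	265	271	0.39	0.48	0.61	60.14	1.74	0.65
DTR	WW20	278.58	4.84	265	289	0.33	1.75	1.78	96.64	8.41	3.02
DTR	DS20	272.82	5.60	254	285	0.28	2.03	2.05	98.14	9.64	3.53
PH	WW17	108.20	19.35	41.33	157.55	6.11	18.04	19.05	89.73	32.55	30.08
PH	DS17	86.58	14.25	61.14	141.33	12.16	16.56	20.54	64.97	20.33	23.49
PH	WW18	178.24	2.37	123.45	141.33	0.84	0.78	1.15	46.38	2.80	0.94
PH	DS18	170.60	5.09	111.11	130.45	1.06	1.77	2.06	73.47	7.74	2.67
PH	WW20	142.31	12.50	113.34	173.12	2.09	8.81	9.05	94.69	21.47	15.09
PH	DS20	122.21	8.80	100.43	154.32	2.15	7.18	7.50	91.80	14.81	12.11
BNPP	WW17	84.21	9.92	29	92	7.09	11.76	13.73	73.31	14.92	17.72
BNPP	DS17	28.10	4.16	23	47	8.19	14.69	16.82	76.28	6.35	22.58
BNPP	WW18	168.53	12.20	125	193	4.70	7.37	8.75	71.06	18.43	10.94
BNPP	DS18	143.06	12.13	115	172	4.75	8.55	9.78	76.43	18.83	13.16
BNPP	WW20	181.23	12.35	149	218	1.85	6.94	7.18	93.34	21.39	11.80
BNPP	DS20	156.10	10.48	129	186	2.58	6.66	7.15	86.96	17.07	10.94
PW	WW17	1599.65	543.50	575.76	3575.42	27.57	33.64	43.50	59.82	732.57	45.80
PW	DS17	472.43	256.80	120.45	1535.34	41.01	53.89	67.72	63.33	356.62	75.49
PW	WW18	2421.35	530.42	665.45	3900.32	13.29	21.93	25.64	73.14	799.14	33.00
PW	DS18	2302.02	480.84	345.42	3395.33	13	20.73	24.47	71.77	711.41	30.90
PW	WW20	2726.34	589.07	835.24	4130.35	11.95	21.65	24.73	76.66	909.55	33.36
PW	DS20	1818.87	456.85	865.32	3195.46	19.35	25.12	31.71	62.75	636.94	35.02
SL	WW17	7.87	0.85	5.32	10.33	7.23	10.68	12.89	68.55	1.22	15.56
SL	DS17	7.81	0.89	6.14	10.33	4.18	17.45	17.94	94.56	2.33	29.86
SL	WW18	6.85	0.83	5.21	9.53	2.98	11.05	11.45	93.23	1.29	18.78
SL	DS18	6.69	0.64	5.32	9.50	3.75	8.37	9.17	83.26	0.90	13.44
SL	WW20	7.10	0.99	5.12	9.32	1.99	12.76	12.91	97.63	1.58	22.18
SL	DS20	6.44	0.90	4.52	9.39	2.71	12.96	13.24	95.81	1.44	22.32
SNPS	WW17	23.53	3.82	19	32	4.55	16.19	16.82	92.68	6.46	27.44
SNPS	DS17	24.50	4.08	17	39	2.19	16.65	16.79	98.30	7.12	29.06
SNPS	WW18	20.52	4.49	11	31	1.97	21.68	21.77	99.18	7.80	38.00
SNPS	DS18	19.73	4.47	11	31	11.15	22.56	25.16	80.38	7.02	35.60
SNPS	WW20	23.40	4.93	11	36	2.63	20.82	20.98	98.43	8.51	36.35
SNPS	DS20	22.05	4.56	11	39	2.47	20.59	20.74	98.58	7.93	35.97
SWPP	WW17	155.71	79.35	20.33	398.45	72.79	51.25	89.02	33.15	80.87	51.93
SWPP	DS17	35.24	16.84	12.45	122.38	64.98	47.97	80.77	35.28	17.67	50.15
SWPP	WW18	135.47	38.37	50.22	235.25	29.71	28.62	41.25	48.14	47.35	34.95
SWPP	DS18	109.01	39.86	33.11	219.42	34.88	36.60	50.56	52.41	50.84	46.63
SWPP	WW20	511.78	143.88	125.43	845.30	23.05	27.98	36.25	59.58	194.53	38.01
SWPP	DS20	120.03	71.82	30.54	375.64	54.77	59.44	80.83	54.08	92.34	76.93
THSW	WW17	2.93	1.07	1.32	6.11	31.29	35.36	47.22	56.09	1.37	46.62
THSW	DS17	2.10	0.85	1.24	4.39	20.19	40.78	45.50	80.32	1.35	64.32
THSW	WW18	3.48	0.68	1.09	4.89	7.79	18.10	19.70	84.38	1.02	29.26
THSW	DS18	2.05	0.65	1.05	3.97	20.30	26.86	33.67	63.64	0.77	37.71
THSW	WW20	4.57	0.57	2.36	6.43	2.60	10.20	10.53	93.89	0.79	17.40
THSW	DS20	4.32	0.59	2.15	7.42	2.81	10.80	11.16	93.67	0.79	18.40
HI	WW17	10.91	6.55	1.32	32.34	51.86	9.5	52.73	3.24	0.33	3.01
HI	DS17	8.53	3.43	3.76	21.46	50.98	39.84	64.70	37.91	3.68	43.17
HI	WW18	5.78	1.75	3.31	13.17	34.31	30.09	45.63	43.48	2.02	34.92
HI	DS18	4.88	1.87	2.70	15.75	40.95	37.74	55.69	45.92	2.20	45.01
HI	WW20	18.73	3.33	7.45	27.33	21.39	17.64	27.72	40.48	3.70	19.75
HI	DS20	6.39	2.70	2.45	16.35	46.58	41.3	62.26	44.01	3.08	48.22
SY	WW17	2594.18	1096.08	396.34	7666.34	25.77	42.10	49.36	72.74	1639.3	63.19
SY	DS17	1918.77	986.37	630.71	7378.25	45.85	57.09	73.22	60.79	1503.2	78.34
SY	WW18	1352.23	383.93	500.22	2350.21	24.32	28.67	37.60	58.16	520.46	38.49
SY	DS18	1088.11	398.32	330.32	2190.25	30.76	36.72	47.90	58.77	539.12	49.55
SY	WW20	5125.42	1443.27	1250.37	8450.23	18.61	28.02	33.64	69.41	2106.05	41.09
SY	DS20	1200.34	718.25	300.34	3750.25	42.13	59.44	72.85	66.55	1024.36	85.34
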