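patient_id	sex	age	tissue	rs4488761_gen	rs4488761_aer	rs2587100_gen	rs2587100_aer	rs9967_gen	rs9967_aer	rs11538_gen	rs11538_aer	rs2277831_gen	rs5992854_gen	rs5992854_aer	rs11917_gen	rs11917_aer	rs1057721_gen	rs1057721_aer	rs4819639_gen	rs4819639_aer
1	F	55	Cart (K)	AG	1.04	CG	0.67	CT	0.71	TC	0.90	GG	CC	-	GG	-	AA	-	CC	-
33	M	74	Cart (K)	AG	1.15	CG	1.03	CT	0.91	TT	-	GG	CC	-	GG	-	AA	-	CC	-
3	M	82	Cart (K)	AA	-	CG	0.83	TT	-	TC	1.10	GA	TC	1.13	GG	-	AA	-	CT	0.96
4	M	57	Cart (K)	AG	0.95	CG	0.87	CT	1.09	TC	1.06	GA	TC	0.56	TG	1.30	GA	2.10	CT	1.38
34	F	57	Cart (K)	AA	-	GG	-	TT	-	TT	-	GA	TC	1.14	TG	0.88	GA	0.84	CT	0.90
35	M	58	Cart (K)	AA	-	CG	0.78	TT	-	TT	-	GA	TC	1.30	TG	1.11	GA	0.87	CT	1.02
36	M	71	Cart (K)	GG	-	GG	-	CC	-	TT	-	GA	TC	1.02	GG	-	AA	-	CC	-
37	F	72	Cart (K)	AG	1.09	CG	0.91	CT	1.15	TC	1.54	AA	TT	-	TG	1.51	GA	0.85	CT	0.87
38	M	64	Cart (K)	AG	0.91	CG	1.01	CT	1.09	TT	-	AA	TC	5.47	TT	-	GG	-	CC	-
39	M	76	Cart (K)	GG	-	CG	0.88	CT	1.33	TT	-	AA	TT	-	TG	1.01	GA	1.51	CT	0.82
13	F	66	Cart (K)	AG	1.40	CG	2.82	CT	0.57	TT	-	AA	TC	1.22	TT	-	GG	-	TT	-
26	F	67	Cart (H)	AG	1.67	CG	1.98	CT	1.01	TT	-	AA	TC	0.83	TT	-	GG	-	TT	-
40	F	76	Cart (H)	AG	1.04	CG	0.99	CT	1.22	TC	1.01	AA	TT	-	TG	0.76	GA	1.14	CT	1.49
41	F	50	Cart (H)	GG	-	CG	0.94	CC	-	TT	-	AA	TT	-	TT	-	GG	-	CT	0.83
42	M	83	Cart (H)	AG	0.97	CG	1.00	CT	1.18	TC	0.96	AA	TC	1.03	TG	1.00	GA	1.16	CT	0.93
43	M	62	Fat pad	AG	1.06	CG	1.00	CT	1.01	TC	0.94	GG	CC	-	TG	1.09	GA	1.39	CC	-
44	M	57	Fat pad	AG	1.01	GG	-	CT	0.80	TT	-	GG	TT	-	GG	-	AA	-	CC	-
45	M	76	Fat pad	GG	-	GG	-	CC	-	TT	-	GA	TC	1.92	GG	-	AA	-	CC	-
46	M	79	Fat pad	GG	-	GG	-	CC	-	TT	-	GA	TC	0.96	TG	1.03	GA	1.13	CT	1.02
47	M	58	Fat pad	AG	0.99	CC	-	TT	-	TT	-	GA	TT	-	GG	-	AA	-	CC	-
48	M	58	Fat pad	AG	1.02	CG	1.00	CT	1.36	TT	-	AA	TT	-	TG	0.80	GA	0.63	CT	1.09
49	F	42	Fat pad	AG	1.05	CG	0.94	CT	1.15	TT	-	AA	TT	-	TG	2.13	GA	1.22	CT	0.92
50	M	71	Fat pad	GG	-	CG	1.00	CT	1.13	TT	-	AA	TT	-	TG	1.27	GA	1.23	CC	-
51	F	67	Fat pad	AG	0.95	CG	1.05	CT	0.95	TT	-	AA	TC	0.75	TT	-	GG	-	TT	-
52	F	78	Fat pad	AG	1.15	CG	0.89	CT	0.92	TT	-	AA	TT	-	GG	-	AA	-	CC	-
53	M	74	Syn	AG	0.80	GG	-	CT	1.33	TT	-	GG	CC	-	GG	-	AA	-	CC	-
54	M	62	Syn	AG	0.99	CG	0.85	CT	1.23	TT	-	GA	TC	1.12	GG	-	AA	-	CC	-
55	M	67	Syn	AG	0.97	CG	0.98	CT	1.32	TC	0.83	GA	TC	0.81	TG	0.57	GA	0.75	CT	1.24
56	M	60	Syn	AG	1.11	GG	-	CT	1.14	TT	-	AA	TT	-	TG	1.19	GA	1.32	CC	-
57	M	69	Syn	AG	0.85	CG	1.98	CT	0.72	TC	2.09	AA	TT	-	TT	-	GG	-	CT	0.77
58	F	54	Syn	AG	0.90	CG	1.16	CT	1.19	TC	1.56	AA	TT	-	TG	1.85	GA	1.89	CC	-
52	F	78	Syn	AG	1.00	CG	0.95	CT	1.02	TT	-	AA	TT	-	GG	-	AA	-	CC	-
59	F	72	Can bn	AA	-	CG	1.10	TT	-	TC	1.14	GA	TC	0.96	TG	0.86	GA	1.23	CT	1.07
60	M	86	Can bn	GG	-	GG	-	CC	-	TT	-	AA	TT	-	TG	1.43	GA	1.10	CC	-
60	M	86	OP	GG	-	GG	-	CC	-	TT	-	AA	TT	-	TG	1.27	GA	1.31	CC	-
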