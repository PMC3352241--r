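country	ln_meanlog	ln_sdlog	gamma_scale	gamma_shape	weibull_scale	weibull_shape	n	emp_mean	emp_sd	ln_mean	ln_sd	gamma_mean	gamma_sd	weibull_mean	weibull_sd
Argentina	1.84	1.68	25.33	0.64	13.62	0.75	359	16.26	21.80	25.79	102.88	16.26	20.29	16.29	22.18
Australia	1.63	1.69	18.79	0.67	10.99	0.78	882	12.63	15.09	21.31	86.21	12.63	15.40	12.73	16.58
Austria	2.85	0.96	19.72	1.33	27.52	1.13	2697	26.23	26.25	27.23	33.35	26.23	22.75	26.35	23.43
Belize	2.06	1.55	37.69	0.59	16.85	0.69	957	22.52	41.05	26.19	83.46	22.31	29.00	21.51	31.79
Brazil	1.57	2.01	47.07	0.44	12.55	0.57	325	20.78	37.89	35.81	265.46	20.78	31.27	20.16	37.64
Canada	1.96	1.42	21.64	0.74	14.04	0.81	4833	16.09	24.60	19.65	50.51	16.02	18.62	15.84	19.82
Costa Rica	1.13	1.87	23.50	0.49	7.71	0.61	285	11.47	18.97	17.91	101.55	11.47	16.42	11.30	19.36
Czech Republic	2.58	1.55	38.84	0.75	26.59	0.83	1121	29.19	32.98	43.56	137.44	29.19	33.67	29.27	35.28
Denmark	2.28	1.24	18.05	0.98	17.33	0.96	865	17.68	21.18	21.03	39.93	17.68	17.87	17.66	18.42
ECAS: Finland	2.22	1.18	16.68	0.99	16.13	0.95	462	16.53	21.56	18.48	32.09	16.53	16.60	16.49	17.32
ECAS: France	2.18	1.48	26.19	0.75	17.56	0.82	415	19.75	28.51	26.44	74.41	19.66	22.69	19.55	23.98
ECAS: Germany	1.92	1.33	16.43	0.84	12.84	0.87	328	13.81	19.83	16.65	36.89	13.81	15.06	13.73	15.76
ECAS: Italy	2.22	1.40	20.68	0.87	17.43	0.92	434	18.06	19.09	24.71	61.39	18.06	19.33	18.08	19.57
ECAS: Sweden	1.79	1.26	13.48	0.87	10.94	0.88	449	11.77	17.59	13.28	26.13	11.77	12.60	11.66	13.29
ECAS: UK	2.85	1.30	38.19	0.88	31.78	0.90	361	34.95	54.61	40.33	85.07	33.62	35.83	33.48	37.34
Finland	1.76	1.51	17.08	0.75	11.58	0.83	864	12.88	17.32	18.14	53.44	12.88	14.83	12.84	15.63
France	2.44	1.25	25.29	0.88	21.08	0.90	4697	22.24	25.21	24.83	47.92	22.24	23.72	22.18	24.67
Germany	2.27	1.37	21.29	0.88	18.07	0.92	3510	18.79	20.74	24.77	58.38	18.79	20.00	18.79	20.45
Hungary	1.10	1.81	17.13	0.55	6.95	0.67	991	9.38	15.16	15.50	78.87	9.38	12.68	9.25	14.34
Iceland	1.64	1.25	9.84	0.96	9.17	0.95	1013	9.42	11.04	11.18	21.62	9.42	9.63	9.40	9.94
India	2.24	1.95	69.20	0.49	23.75	0.62	498	34.82	54.78	63.16	417.87	34.20	48.65	34.40	58.26
Ireland	3.04	1.18	38.57	0.98	36.94	0.95	385	37.82	43.73	42.23	73.86	37.82	38.19	37.74	39.61
Isle of Man	2.22	1.78	39.38	0.63	20.51	0.74	420	24.90	36.39	45.31	217.60	24.64	31.15	24.77	34.16
Israel	1.02	1.87	22.11	0.48	6.85	0.61	2005	10.59	19.71	15.91	89.50	10.59	15.30	10.19	17.71
Italy	2.44	1.30	21.80	0.96	20.92	0.99	1429	20.98	19.35	26.89	56.90	20.98	21.39	20.98	21.13
Japan	1.63	2.19	37.45	0.49	13.60	0.63	1009	18.51	25.29	55.72	605.09	18.51	26.33	19.42	32.43
Kazakhstan	1.87	1.76	36.80	0.55	14.69	0.67	401	20.55	40.31	30.49	139.45	20.27	27.31	19.50	30.13
Mexico	1.34	1.90	33.23	0.46	9.68	0.59	1833	15.48	30.37	23.46	141.72	15.37	22.60	14.86	26.61
Netherlands	2.28	1.17	17.45	1.00	17.27	0.98	1679	17.47	18.78	19.46	33.31	17.47	17.46	17.46	17.89
Nicaragua	2.03	1.52	38.43	0.58	16.28	0.68	263	22.26	40.29	24.27	73.44	22.26	29.25	21.16	31.91
Nigeria	2.47	1.78	55.90	0.60	26.97	0.71	439	33.63	45.76	58.17	279.62	33.38	43.19	33.66	48.39
Norway	1.66	1.44	15.92	0.74	10.25	0.80	945	11.78	19.42	14.67	38.42	11.78	13.70	11.59	14.57
Peru	1.13	1.17	8.89	0.76	5.60	0.79	425	6.76	15.68	6.10	10.43	6.76	7.75	6.42	8.24
Spain	2.28	1.49	25.30	0.81	19.04	0.87	603	20.44	24.47	29.64	84.47	20.44	22.74	20.43	23.56
Sri Lanka	1.30	2.18	57.93	0.37	10.71	0.51	323	21.87	43.99	39.56	426.76	21.65	35.42	20.87	45.74
Sweden	1.12	1.32	8.20	0.79	5.83	0.83	2348	6.49	9.17	7.30	15.79	6.49	7.30	6.42	7.74
Switzerland	2.37	1.12	17.65	1.05	18.27	0.97	5126	18.55	24.86	20.15	32.01	18.54	18.09	18.50	19.05
Uganda	2.75	1.79	70.07	0.61	35.42	0.73	378	42.93	52.50	78.02	382.06	42.80	54.76	43.42	61.01
Uruguay	1.69	1.84	34.78	0.52	12.88	0.64	305	18.32	34.55	29.22	154.64	18.16	25.14	17.75	28.56
USA 2	1.41	1.72	25.65	0.53	9.50	0.64	1499	13.51	24.00	17.81	75.66	13.51	18.62	13.12	21.16
USA 3	1.32	1.80	28.58	0.49	9.04	0.61	2300	14.18	32.43	19.12	95.29	13.93	19.95	13.20	22.54
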