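country	ln_meanlog	ln_sdlog	gamma_scale	gamma_shape	weibull_scale	weibull_shape	n	emp_mean	emp_sd	ln_mean	ln_sd	gamma_mean	gamma_sd	weibull_mean	weibull_sd
Argentina	0.14	1.93	9.17	0.48	2.92	0.60	381	4.38	6.77	7.35	46.50	4.38	6.34	4.39	7.69
Australia	0.57	1.88	11.75	0.51	4.33	0.64	1172	6.04	9.52	10.40	60.39	6.04	8.42	6.06	9.90
Australia 1	0.47	1.57	8.57	0.56	3.55	0.67	3002	4.84	7.81	5.47	17.86	4.84	6.44	4.69	7.22
Austria	1.91	0.92	8.45	1.26	10.85	1.05	1916	10.62	13.26	10.36	11.94	10.62	9.47	10.66	10.20
Belize	0.64	1.51	13.44	0.50	4.17	0.62	386	6.74	16.63	5.92	17.44	6.74	9.52	5.98	10.02
Brazil	1.09	2.10	36.30	0.41	8.18	0.54	283	14.80	29.63	26.75	240.21	14.80	23.18	14.27	28.60
Canada	1.06	1.41	9.92	0.69	5.78	0.77	5850	6.88	10.79	7.82	19.76	6.88	8.26	6.75	8.90
Costa Rica	-0.28	1.81	7.20	0.45	1.88	0.57	367	3.21	6.33	3.90	19.86	3.21	4.81	3.00	5.57
Czech Republic	1.04	1.70	16.47	0.54	6.49	0.66	1023	8.97	15.12	12.08	50.02	8.97	12.16	8.74	13.71
Denmark	1.37	1.40	9.37	0.84	7.46	0.89	1042	7.89	8.85	10.48	26.03	7.89	8.59	7.89	8.85
ECAS: Finland	1.07	1.20	6.51	0.88	5.26	0.87	469	5.71	9.65	6.00	10.77	5.71	6.09	5.63	6.47
ECAS: France	0.94	1.56	10.94	0.63	5.51	0.72	382	6.85	9.83	8.64	27.71	6.85	8.66	6.77	9.54
ECAS: Germany	1.05	1.34	9.21	0.72	5.53	0.78	512	6.93	21.77	7.05	15.85	6.62	7.80	6.39	8.30
ECAS: Italy	1.37	1.59	15.91	0.64	8.45	0.74	404	10.23	14.99	14.08	48.17	10.23	12.76	10.17	13.94
ECAS: Sweden	0.90	1.17	4.23	1.02	4.30	0.99	433	4.32	4.58	4.87	8.35	4.32	4.28	4.32	4.36
ECAS: UK	1.70	1.48	19.03	0.69	11.13	0.77	498	13.14	19.31	16.34	46.06	13.14	15.81	12.97	17.02
Finland	0.47	1.67	7.08	0.61	3.47	0.72	882	4.35	7.83	6.45	25.27	4.35	5.55	4.28	6.07
France	1.62	1.05	9.30	0.98	8.75	0.92	4206	9.14	11.79	8.78	12.42	9.14	9.22	9.08	9.83
Germany	1.30	1.47	12.42	0.70	7.43	0.78	4164	8.72	12.97	10.88	30.24	8.72	10.41	8.60	11.17
Hungary	-0.82	1.89	4.36	0.44	1.11	0.58	883	1.92	5.31	2.62	15.31	1.92	2.90	1.75	3.22
Iceland	0.82	1.31	5.78	0.81	4.23	0.84	1072	4.70	7.41	5.34	11.37	4.70	5.21	4.63	5.53
India	1.31	2.16	42.29	0.42	10.39	0.55	85	17.67	26.94	38.01	388.74	17.67	27.33	17.88	35.44
Ireland	2.01	1.23	15.55	0.91	13.53	0.91	378	14.20	17.69	16.05	30.35	14.20	14.86	14.14	15.54
Isle of Man	1.18	1.85	16.98	0.57	7.59	0.69	469	9.67	13.20	17.91	97.33	9.67	12.81	9.77	14.57
Israel	-0.05	1.98	12.55	0.40	2.52	0.54	1938	4.98	12.52	6.70	46.91	4.98	7.91	4.46	9.04
Italy	1.52	1.39	12.97	0.77	8.95	0.83	1219	9.93	11.72	11.91	28.76	9.93	11.35	9.90	12.01
Japan	-0.15	2.18	14.32	0.37	2.53	0.50	864	5.27	11.72	9.17	97.39	5.27	8.68	5.02	11.15
Kazakhstan	-0.52	1.93	6.67	0.42	1.52	0.56	401	2.80	7.91	3.78	23.87	2.80	4.32	2.50	4.78
Mexico	-1.15	1.63	5.03	0.37	0.76	0.53	1406	1.88	7.32	1.20	4.39	1.88	3.07	1.37	2.82
Netherlands	1.44	1.11	8.33	0.94	7.43	0.91	1505	7.84	10.50	7.83	12.20	7.84	8.08	7.78	8.58
Nicaragua	0.91	1.49	26.83	0.43	5.54	0.57	147	11.43	34.88	7.52	21.56	11.43	17.51	8.94	16.78
Nigeria	1.84	2.31	65.85	0.43	18.29	0.56	200	28.45	41.91	91.55	1322.58	28.45	43.28	30.12	57.50
Norway	0.61	1.58	7.07	0.66	3.85	0.75	1004	4.64	7.03	6.39	21.38	4.64	5.73	4.59	6.21
Peru	0.16	0.91	1.62	1.18	1.89	0.98	620	1.91	3.07	1.78	2.03	1.91	1.76	1.90	1.95
Spain	1.07	1.78	13.31	0.61	6.58	0.72	427	8.07	11.17	14.34	69.00	8.07	10.36	8.12	11.50
Sri Lanka	-2.28	1.69	3.31	0.30	0.27	0.46	38	1.00	2.93	0.42	1.70	1.00	1.82	0.64	1.63
Sweden	0.44	1.26	4.15	0.79	2.93	0.83	2226	3.29	4.51	3.42	6.75	3.29	3.69	3.24	3.94
Switzerland	1.39	1.25	8.07	0.93	7.21	0.93	5362	7.50	10.07	8.77	17.04	7.50	7.78	7.48	8.09
Uganda	0.98	2.09	34.50	0.40	7.39	0.53	280	13.78	26.60	23.46	206.14	13.78	21.80	13.25	27.17
Uruguay	0.19	1.90	11.60	0.45	3.10	0.58	375	5.17	12.02	7.35	43.87	5.17	7.75	4.91	9.05
USA 1	0.18	1.96	12.42	0.43	3.16	0.56	854	5.37	10.39	8.11	54.33	5.37	8.17	5.21	9.95
USA 2	0.30	1.62	11.49	0.47	3.12	0.59	1310	5.35	14.44	5.00	17.90	5.35	7.84	4.76	8.46
USA 3	0.23	1.67	9.85	0.48	2.94	0.61	2274	4.75	10.65	5.09	19.93	4.75	6.84	4.36	7.57
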