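trait	mean_umol_l	sd_umol_l	direction	p_adj	r2_adj	p_gain	internally_consistent
Val	227.26	53.13	pos	4.75e-16	0.16
Glu	80.13	32.04	pos	1.22e-15	0.11
Ile	72.14	20.22	pos	1.96e-11	0.22
Leu	160.51	44.33	pos	2.57e-08	0.18
Ala	417.99	101.4	pos	8.95e-06	0.03
Tyr	72.09	20.06	pos	4.77e-10	0.06
Phe	76.73	17.19	pos	2.53e-07	0.05
Sum aromatic AAs	208.98	43.75	pos	3.37e-09	0.07
Sum BCAAs	459.91	113.06	pos	2.07e-13	0.19
Ile/Gly	0.29	0.11	pos	1.61e-14	0.30	1.22e+03	1
Leu/Gly	0.65	0.25	pos	1.46e-12	0.29	1.75e+04	0
Sum BCAAs/Sum glucogenic AAs	0.58	0.14	pos	1.49e-08	0.26
C5	0.16	0.06	pos	3.49e-05	0.17
C3	0.47	0.15	pos	4.85e-05	0.13
C0	40.52	8.49	pos	1.19e-02	0.13
C18	0.06	0.01	neg	3.96e-02	0.10
C18/C5	0.37	0.14	neg	1.44e-09	0.08	2.42e+04	1
C18/C3	0.13	0.05	neg	3.65e-09	0.05	1.33e+04	1
C18/C0	0.001	0.0004	neg	5.44e-07	0.05	2.19e+04	1
PC aa C38:3	57.77	14.01	pos	7.02e-06	0.06
PC ae C42:3	0.85	0.19	neg	5.10e-18	0.10
PC ae C36:2	15.33	3.88	neg	2.42e-15	0.19
lysoPC a C18:2	28.46	9.04	neg	8.19e-16	0.16
lysoPC a C18:1	21.61	6.1	neg	2.30e-10	0.11
Sum PC ae	181.45	30.52	neg	1.38e-04	0.10
Sum lysoPC	229.29	47.21	neg	4.36e-04	0.07
PC aa C38:3/PC aa C42:6	97.71	21.87	pos	1.04e-17	0.09	6.73e+11	0
PC aa C38:3/PC aa C42:1	228.35	80.97	pos	6.09e-15	0.07	1.15e+07	0
PC aa C38:3/PC aa C42:0	111.66	41.58	pos	1.06e-15	0.07	3.68e+06	0
PC aa C38:3/PC aa C42:2	297.65	96.51	pos	1.72e-16	0.10	1.69e+09	0
lysoPC a C14:0/lysoPC a C18:2	0.24	0.08	pos	1.04e-20	0.18	7.88e+04	1
PC ae C36:4/PC ae C40:1	12.99	3.34	pos	1.70e-07	0.04	3.57e+02	0
PC aa C38:3/lysoPC a C18:1	2.27	0.99	pos	3.37e-20	0.19	2.43e+04	0
PC aa C38:3/lysoPC a C18:2	2.87	1.03	pos	1.38e-19	0.17	1.66e+09	0
PC aa C38:3/PC ae C42:3	70.43	21.88	pos	3.12e-26	0.12	1.63e+08	1
PC aa C38:3/PC ae C36:2	3.98	1.36	pos	8.17e-25	0.13	2.96e+09	1
PC aa C38:3/PC ae C42:2	93.08	24.28	pos	3.73e-23	0.11	7.97e+15	0
SM C16:0/SM C16:1	6.4	0.76	neg	1.52e-11	0.29	3.13e+08	0
SM (OH) C16:1/SM C18:1	0.31	0.06	neg	3.51e-10	0.05	4.94e+07	0
SM C16:0/SM C18:1	9.36	1.83	neg	5.71e-08	0.24	8.33e+04	0
SM (OH) C16:1/SM C18:0	0.16	0.03	neg	3.28e-10	0.10	5.27e+07	0
SM (OH) C22:2/SM C18:1	1.00	0.19	neg	4.14e-07	0.05	2.93e+05	0
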