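residue	N	HN	HA	HB	HG	HD
A1	119.11	7.90
Q2	115.05	7.34	4.35	1.96
R3	118.85	7.20	4.00	1.68
S4	119.71	7.76	4.70	3.85
S5	121.19	7.66	4.15	3.95
A6	119.78	7.29	4.06	1.48
E7	115.90	7.15	4.00	_
T8	119.64	7.72	4.07	4.05	1.20
N9	117.40	7.56	4.10	2.70
E10	119.06	8.43	3.97	1.88
L11	121.01	8.00	4.37	1.70
R12	123.40	8.91	4.60	1.61
E13	117.83	8.64	3.80	1.90
A14	121.51	8.96	4.60	_
L15	128.80	8.82	4.60	2.04
L16	120.89	9.30	4.60	_
K17	123.89	8.31	4.24	1.59
I18	120.30	8.60	4.13	_	1.00
F19	124.40	7.80	4.38	3.06
D21	119.80	8.43	4.38	2.74
S22	119.90	8.73	_	3.79
E23	121.33	9.10	4.60	2.08
Q24	119.20	8.08	4.10	2.07
R25	119.90	8.59	4.13	1.85
L26	115.70	8.13	4.30	_
K27	113.42	7.26	4.06	1.91
I28	118.24	7.17	3.79	1.45	0.83	0.04
D29	118.87	6.87	4.70	2.93
Q30	119.40	8.11	3.90	2.00
I31	119.30	7.83	4.10	_	0.08 (Hγ2)	−0.08
L32	119.75	7.41	3.31	_
V33	115.36	8.37	4.57	2.90
H35	115.36	8.37	3.14	3.14
Y37	119.73	8.01	5.10	3.01
M38	117.95	7.47	4.10	2.70
K39	118.38	8.04	4.08	_
D40	124.90	7.46	4.36	2.66
L41	113.90	8.55	4.05	_
N42	120.64	8.20	4.70	2.86
A43	121.92	7.37	4.67	1.40
L44	118.16	7.64	4.15	_
S45	118.32	8.37	4.58	3.97		0.9 (Hδ1,2)
A46	119.77	7.29	4.05	1.40
M47	119.80	7.05	4.27	2.04	2.52
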