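participant	trial	te_eye_to_head_x100	te_head_to_eye_x100
1	1	2.19	2.98
1	2	1.99	2.77
1	3	1.68	1.85
1	4	1.75	2.99
2	1	1.82	3.03
2	2	2.6	6.93
2	3	1.64	3.52
2	4	2	4.76
3	1	2.25	3.68
3	2	1.97	2.58
3	3	2.42	2.72
3	4	2.66	4.48
4	1	0.79	1.97
4	2	1.25	2.23
4	3	1.31	3.16
4	4	1.17	3.86
5	1	1.82	4.96
5	2	1.13	5.87
5	3	0.86	7.66
5	4	1.59	3.84
6	1	1.83	5.38
6	2	4.28	8.71
6	3	2.06	5.09
6	4	1.99	3.96
7	1	1.45	4.36
7	2	2.99	6.41
7	3	2.26	6.6
7	4	1.09	4.74
8	1	1.39	2.31
8	2	1.49	3.51
8	3	3	6.86
8	4	2.31	3.88
9	1	1.76	5.09
9	2	2.17	6.5
9	3	1.85	5.6
9	4	2.16	3.79
10	1	1.12	1.8
10	2	1.23	4.3
10	3	1.08	2.99
10	4	1.86	4.95
11	1	2.27	5.02
11	2	1.22	2.43
11	3	2.09	3.98
11	4	1.1	2.8
12	1	1.32	3.58
12	2	2.34	7.87
12	3	2.81	8.99
12	4	2.36	9.37
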