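participant	trial	nuid_x100	performance_s2_per_m
1	1	-1.75	0.37
1	2	-1.13	0.43
1	3	-0.35	0.42
1	4	-0.18	0.34
2	1	1.23	0.71
2	2	2.77	0.64
2	3	3.11	0.69
2	4	5.05	0.89
3	1	1.66	0.45
3	2	1.65	0.41
3	3	-0.8	0.42
3	4	-0.28	0.4
4	1	4.85	0.72
4	2	1.5	0.56
4	3	4.45	0.56
4	4	4.84	0.52
5	1	5.95	0.44
5	2	6.02	0.48
5	3	8.07	0.42
5	4	4.47	0.55
6	1	4.18	0.25
6	2	-1.42	0.29
6	3	3	0.3
6	4	0.88	0.3
7	1	6.28	0.56
7	2	0.6	0.52
7	3	5.17	0.64
7	4	8.2	0.57
8	1	-2.54	0.35
8	2	2.15	0.46
8	3	2.58	0.4
8	4	0.91	0.4
9	1	3.4	0.62
9	2	1.25	0.44
9	3	-0.99	0.4
9	4	-1.04	0.47
10	1	3.21	0.44
10	2	7.97	0.51
10	3	8.45	0.36
10	4	5.93	0.5
11	1	4.76	0.45
11	2	2.41	0.42
11	3	4.12	0.44
11	4	3.15	0.38
12	1	2.39	0.64
12	2	2.69	0.59
12	3	4.35	0.55
12	4	2.93	0.71
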