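participant	trial	uid_x100
1	1	0.79
1	2	0.78
1	3	0.17
1	4	1.24
2	1	1.21
2	2	4.33
2	3	1.88
2	4	2.76
3	1	1.43
3	2	0.61
3	3	0.3
3	4	1.82
4	1	1.18
4	2	0.98
4	3	1.85
4	4	2.7
5	1	3.14
5	2	4.73
5	3	6.8
5	4	2.25
6	1	3.55
6	2	4.43
6	3	3.02
6	4	1.97
7	1	2.91
7	2	3.42
7	3	4.33
7	4	3.65
8	1	0.91
8	2	2.02
8	3	3.86
8	4	1.57
9	1	3.33
9	2	4.33
9	3	3.75
9	4	1.62
10	1	0.68
10	2	3.06
10	3	1.91
10	4	3.09
11	1	2.76
11	2	1.21
11	3	1.89
11	4	1.7
12	1	2.26
12	2	5.53
12	3	6.18
12	4	7.01
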