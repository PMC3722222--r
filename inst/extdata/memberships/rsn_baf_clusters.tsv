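row	cluster
2	1
22	1
9	1
5	1
4	2
7	2
21	2
18	3
20	4
25	5
14	5
17	5
32	5
27	6
28	6
11	6
29	6
13	6
19	6
6	6
26	6
18	6
20	6
8	6
24	6
3	7
15	7
30	7
16	7
31	8
23	9
1	10
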