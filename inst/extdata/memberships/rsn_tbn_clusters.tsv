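row	cluster
2	1
5	1
22	1
9	1
20	2
7	2
18	2
21	2
4	3
14	4
25	4
32	5
17	5
27	5
6	6
1	6
23	6
24	6
13	6
29	6
3	6
28	6
30	6
11	6
19	6
31	6
26	6
8	6
16	6
15	6
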