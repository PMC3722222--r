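row	cluster
1	1
23	1
2	1
5	1
22	1
9	1
20	2
21	2
4	3
7	3
18	3
14	4
25	4
27	4
32	4
17	4
24	5
13	5
29	5
28	5
30	5
11	5
19	5
31	5
26	5
16	5
3	6
15	6
6	7
8	7
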