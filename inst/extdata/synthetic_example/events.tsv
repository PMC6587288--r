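generation	population	event	n
1	1	fission	8
1	2	fission	8
2	1	fission	8
2	2	fission	8
3	1	fission	8
3	2	fission	8
4	1	fission	8
4	2	fission	8
5	1	fission	8
5	2	fission	8
6	1	fission	8
6	2	fission	8
7	1	fission	8
7	2	fission	8
8	1	fission	8
8	2	fission	8
9	1	fission	8
9	2	fission	8
10	1	fission	8
10	2	fission	8
11	1	fission	8
11	2	fission	8
12	1	fission	8
12	2	fission	8
13	1	fission	8
13	2	fission	8
14	1	fission	8
14	2	fission	8
15	1	fission	8
15	2	fission	8
16	1	fission	8
16	2	fission	8
17	1	fission	8
17	2	fission	8
18	1	fission	8
18	2	fission	8
19	1	fission	8
19	2	fission	8
20	1	fission	8
20	2	fission	8
21	1	fission	8
21	2	fission	8
22	1	fission	8
22	2	fission	8
23	1	fission	8
23	2	fission	8
24	1	fission	8
24	2	fission	8
25	1	fission	8
25	2	fission	8
26	1	fission	8
26	2	fission	8
27	1	fission	8
27	2	fission	8
28	1	fission	8
28	2	fission	8
29	1	fission	8
29	2	fission	8
30	1	fission	8
30	2	fission	8
31	1	fission	8
31	2	fission	8
32	1	fission	8
32	2	fission	8
33	1	fission	8
33	2	fission	8
34	1	fission	8
34	2	fission	8
35	1	fission	8
35	2	fission	8
36	1	fission	8
36	2	fission	8
37	1	fission	8
37	2	fission	8
38	1	fission	8
38	2	fission	8
39	1	fission	8
39	2	fission	8
40	1	fission	8
40	2	fission	8
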