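Re-sort ID	ERCC ID	subgroup	concentration in Mix 1 (attomoles/ul)	length
1	ERCC-00001	A	0.01000000	621
2	ERCC-00002	B	0.01163949	1110
3	ERCC-00003	C	0.01354778	1114
4	ERCC-00004	D	0.01576893	314
5	ERCC-00005	A	0.01835423	853
6	ERCC-00006	B	0.02136340	1846
7	ERCC-00007	C	0.02486591	584
8	ERCC-00008	D	0.02894266	572
9	ERCC-00009	A	0.03368779	871
10	ERCC-00010	B	0.03921088	1249
11	ERCC-00011	C	0.04563948	781
12	ERCC-00012	D	0.05312204	1250
13	ERCC-00013	A	0.06183136	1633
14	ERCC-00014	B	0.07196857	533
15	ERCC-00015	C	0.08376776	1430
16	ERCC-00016	D	0.09750143	431
17	ERCC-00017	A	0.11348672	646
18	ERCC-00018	B	0.13209279	1432
19	ERCC-00019	C	0.15374931	905
20	ERCC-00020	D	0.17895641	859
21	ERCC-00021	A	0.20829619	1840
22	ERCC-00022	B	0.24244620	1406
23	ERCC-00023	C	0.28219509	1641
24	ERCC-00024	D	0.32846078	528
25	ERCC-00025	A	0.38231169	1474
26	ERCC-00026	B	0.44499143	642
27	ERCC-00027	C	0.51794747	430
28	ERCC-00028	D	0.60286460	754
29	ERCC-00029	A	0.70170383	902
30	ERCC-00030	B	0.81674768	568
31	ERCC-00031	C	0.95065290	1096
32	ERCC-00032	D	1.10651179	274
33	ERCC-00033	A	1.28792363	636
34	ERCC-00034	B	1.49907781	1749
35	ERCC-00035	C	1.74485058	497
36	ERCC-00036	D	2.03091762	1465
37	ERCC-00037	A	2.36388516	409
38	ERCC-00038	B	2.75144249	1787
39	ERCC-00039	C	3.20253958	543
40	ERCC-00040	D	3.72759372	820
41	ERCC-00041	A	4.33873013	1246
42	ERCC-00042	B	5.05006192	1783
43	ERCC-00043	C	5.87801607	1427
44	ERCC-00044	D	6.84171273	603
45	ERCC-00045	A	7.96340679	696
46	ERCC-00046	B	9.26900181	1989
47	ERCC-00047	C	10.78864823	1476
48	ERCC-00048	D	12.55743963	581
49	ERCC-00049	A	14.61622315	1631
50	ERCC-00050	B	17.01254280	1947
51	ERCC-00051	C	19.80173739	1133
52	ERCC-00052	D	23.04821851	1262
53	ERCC-00053	A	26.82695795	351
54	ERCC-00054	B	31.22521911	1673
55	ERCC-00055	C	36.34457213	747
56	ERCC-00056	D	42.30323953	978
57	ERCC-00057	A	49.23882632	1294
58	ERCC-00058	B	57.31149775	1498
59	ERCC-00059	C	66.70767807	690
60	ERCC-00060	D	77.64435563	1054
61	ERCC-00061	A	90.37409390	1896
62	ERCC-00062	B	105.19086393	772
63	ERCC-00063	C	122.43683313	667
64	ERCC-00064	D	142.51026703	1815
65	ERCC-00065	A	165.87472650	1149
66	ERCC-00066	B	193.06977289	1132
67	ERCC-00067	C	224.72342828	357
68	ERCC-00068	D	261.56667853	1218
69	ERCC-00069	A	304.45035410	1377
70	ERCC-00070	B	354.36477856	378
71	ERCC-00071	C	412.46263829	278
72	ERCC-00072	D	480.08560184	1745
73	ERCC-00073	A	558.79530338	1298
74	ERCC-00074	B	650.40940590	679
75	ERCC-00075	C	757.04357702	1514
76	ERCC-00076	D	881.16034654	1261
77	ERCC-00077	A	1025.62597437	1370
78	ERCC-00078	B	1193.77664171	1051
79	ERCC-00079	C	1389.49549437	416
80	ERCC-00080	D	1617.30231722	1704
81	ERCC-00081	A	1882.45791071	705
82	ERCC-00082	B	2191.08557989	791
83	ERCC-00083	C	2550.31254144	1047
84	ERCC-00084	D	2968.43451426	1254
85	ERCC-00085	A	3455.10729459	1581
86	ERCC-00086	B	4021.56973981	1772
87	ERCC-00087	C	4680.90331014	1439
88	ERCC-00088	D	5448.33416216	678
89	ERCC-00089	A	6341.58477024	1771
90	ERCC-00090	B	7381.28319614	818
91	ERCC-00091	C	8591.43945805	662
92	ERCC-00092	D	10000.00000000	908
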