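# Synthetic 53-exon map tiling the CDS (1 = A of ATG).
exon	cdna_start	cdna_end
1	1	102
2	103	204
3	205	306
4	307	408
5	409	510
6	511	612
7	613	714
8	715	816
9	817	918
10	919	1020
11	1021	1122
12	1123	1224
13	1225	1326
14	1327	1428
15	1429	1530
16	1531	1632
17	1633	1734
18	1735	1836
19	1837	1938
20	1939	2040
21	2041	2142
22	2143	2244
23	2245	2346
24	2347	2448
25	2449	2550
26	2551	2652
27	2653	2754
28	2755	2856
29	2857	2958
30	2959	3060
31	3061	3162
32	3163	3264
33	3265	3366
34	3367	3468
35	3469	3570
36	3571	3672
37	3673	3774
38	3775	3876
39	3877	3978
40	3979	4080
41	4081	4182
42	4183	4284
43	4285	4386
44	4387	4488
45	4489	4590
46	4591	4692
47	4693	4794
48	4795	4896
49	4897	4998
50	4999	5100
51	5101	5202
52	5203	5304
53	5305	5412
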