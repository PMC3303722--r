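premirna_id	location	N5p	N3p	T5p	T3p	exch_label
hsa-mir-1277	3p:47-68	354	172	201	56	N;T
hsa-mir-376a-2	3p:50-70	428	14	99	54	N;T
hsa-mir-495	3p:50-71	35	19	12	5	N;T
hsa-mir-1303	3p:52-73	19	73	12	10	T
hsa-mir-1306	3p:55-72	94	0	31	0	N;T
hsa-mir-496	3p:56-77	27	0	50	0	N;T
hsa-mir-561	3p:61-82	231	0	40	0	N;T
hsa-mir-659	3p:61-82	123	0	56	0	N;T
hsa-mir-376b	3p:62-83	106	9	32	83	N
hsa-mir-1307	3p:80-101	3512	2369	2002	3544	N
hsa-mir-1273c	5p:10-31	0	53	0	50	N;T
hsa-mir-511-1	5p:16-36	39	903	53	147	N;T
hsa-mir-511-2	5p:16-36	39	903	53	147	N;T
hsa-mir-1247	5p:40-61	67	237	17	41	N;T
hsa-mir-374a	MA:12-33;mi:42-63	2275	36122	2017	35147	N;T
hsa-mir-500a	MA:13-35;mi:52-73	215	1907	72	1834	N;T
hsa-mir-625	MA:15-35;mi:52-73	333	576	87	206	N;T
hsa-mir-136	MA:15-37;mi:49-70	1328	621	530	652	T
hsa-mir-664	mi:11-34;MA:49-71	913	271	398	98	N;T
hsa-mir-144	mi:15-36;MA:52-71	12406	441	1209	113	N;T
hsa-mir-493	mi:16-37;MA:57-78	254	248	1744	727	N;T
hsa-mir-376a-1	mi:7-28;MA:44-64	1646	14	569	54	N;T
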