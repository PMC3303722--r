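premirna_id	location	N5p	N3p	ratio_n53p	T5p	T3p	ratio_t53p	fold_change
hsa-mir-17	MA:14-36;mi:51-72	4767	2266	2.1037	6656	425	15.6612	7.44
hsa-mir-511-1	5p:16-36	39	903	0.0432	53	147	0.3605	8.35
hsa-mir-511-2	5p:16-36	39	903	0.0432	53	147	0.3605	8.35
hsa-mir-423	5p:17-39;3p:53-75	20920	8945	2.3387	1708	6266	0.2726	8.58
hsa-mir-30c-1	MA:17-39;mi:56-77	67040	50	1340.8000	8685	64	135.7031	9.88
hsa-mir-135b	MA:16-38;mi:55-76	360	19	18.9474	171	99	1.7273	10.97
hsa-mir-376a-1	mi:7-28;MA:44-64	1646	14	117.5714	569	54	10.5370	11.16
hsa-mir-376a-2	3p:50-70	428	14	30.5714	99	54	1.8333	16.68
hsa-mir-335	MA:16-38;mi:52-73	3509	110	31.9000	418	264	1.5833	20.15
hsa-mir-30b	MA:17-38;mi:55-76	50988	51	999.7647	3931	89	44.1685	22.64
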