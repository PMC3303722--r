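premirna_id	location	N5p	N3p	T5p	T3p
hsa-mir-136	MA:15-37;mi:49-70	1328	621	530	652
hsa-mir-361	5p:6-27;3p:45-67	1651	2493	1451	1024
hsa-mir-423	5p:17-39;3p:53-75	20920	8945	1708	6266
hsa-mir-376b	3p:62-83	106	9	32	83
hsa-mir-1307	3p:80-101	3512	2369	2002	3544
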