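fragment	pct_n	pct_t
A	50.93	33.25
U	30.72	44.07
AA	3.39	4.67
UA	2.28	4.19
UU	2.16	3.12
AU	1.53	1.23
G	1.40	1.80
AAA	1.07	2.10
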