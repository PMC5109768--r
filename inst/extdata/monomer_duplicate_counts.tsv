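id	variant	copy_number	forward_pct
1	Consensus	2678	46
2	C114Del	486	1
3	T101Del	357	99
4	T39G	242	46
5	A40C	101	56
6	T121A	92	41
7	T74G	78	47
8	T80Del	78	100
9	G84C	78	41
10	C42G	76	53
11	G1A	74	43
12	A110G	65	48
13	A112T	61	38
14	T19C	59	37
15	T39G-C114Del	57	0
16	A151C	56	52
17	G79C	55	53
18	C89T	53	49
19	G1T	46	63
20	T39G-T101Del	41	98
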