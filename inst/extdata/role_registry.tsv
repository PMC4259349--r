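role_id	motif_id	ego_pattern	cross_count	variant	plurality	motif_key
1	1	out	1	c2b	2	000000110
2	2	out	1	b2c	1	000001100
3	4	out	2		1	000001110
4	2	in	1	c2b	1	000001100
5	3	in	1	b2c	2	000100100
6	6	in	2		1	001001010
7	4	recip	1	c2b	1	000001110
8	6	recip	1	b2c	1	001001010
9	8	recip	2		2	001001110
10	1	in+in	0		1	000000110
11	9	in+in	1		1	000100110
12	11	in+in	2		1	001101100
13	3	out+out	0		1	000100100
14	9	out+out	1		1	000100110
15	7	out+out	2		1	000101110
16	2	in+out	0		1	000001100
17	5	in+out	1	cycle	3	001100010
18	9	in+out	1	ffl_mid	1	000100110
19	10	in+out	2		1	001100110
20	6	recip+out	0		1	001001010
21	10	recip+out	1	o2p	1	001100110
22	11	recip+out	1	p2o	2	001101100
23	12	recip+out	2		1	001101110
24	4	recip+in	0		1	000001110
25	7	recip+in	1	o2p	2	000101110
26	10	recip+in	1	p2o	1	001100110
27	12	recip+in	2		1	001101110
28	8	recip+recip	0		1	001001110
29	12	recip+recip	1		1	001101110
30	13	recip+recip	2		3	011101110
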