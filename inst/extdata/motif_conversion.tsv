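# motif-level conversion matrix, structural to functional
functional_id	s1	s2	s3	s4	s5	s6	s7	s8	s9	s10	s11	s12	s13
1	1	0	0	1	0	0	2	1	1	1	1	2	3
2	0	1	0	1	3	1	2	2	1	3	2	4	6
3	0	0	1	0	0	1	1	1	1	1	2	2	3
4	0	0	0	1	0	0	2	2	0	1	0	3	6
5	0	0	0	0	1	0	0	0	0	1	0	1	2
6	0	0	0	0	0	1	0	2	0	1	2	3	6
7	0	0	0	0	0	0	1	0	0	0	0	1	3
8	0	0	0	0	0	0	0	1	0	0	0	1	3
9	0	0	0	0	0	0	2	0	1	1	2	3	6
10	0	0	0	0	0	0	0	0	0	1	0	2	6
11	0	0	0	0	0	0	0	0	0	0	1	1	3
12	0	0	0	0	0	0	0	0	0	0	0	1	6
13	0	0	0	0	0	0	0	0	0	0	0	0	1
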