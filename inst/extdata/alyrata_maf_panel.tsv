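locus	maf	ref_allele	minor_allele
1	0.45	T	T
2	0.40	A	A
3	0.25	A	A
4	0.47	G	A
5	0.45	C	G
6	0.50	G	G/T
7	0.32	C	T
8	0.17	G	G
9	0.40	G	A
10	0.30	A	G
11	0.35	C	T
12	0.47	T	A
13	0.45	C	C
14	0.32	T	T
15	0.50	C	C/T
16	0.50	C	C/T
17	0.45	A	G
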