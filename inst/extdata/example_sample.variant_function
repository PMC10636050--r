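exonic	NOD2	16	50745926	50745926	C	T
exonic	NOD2	16	50756540	50756540	G	A
intronic	NOD2	16	50731780	50731780	T	C
UTR3	IL23R	1	67725120	67725120	A	G
splicing	ATG16L1	2	234183368	234183368	G	C
intronic	IRGM;LRRK2	5	150226910	150226910	C	G
intergenic	NONE	3	1000	1000	A	T
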