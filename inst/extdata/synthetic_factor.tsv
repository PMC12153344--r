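motif_class	aa5	aa_last
P	T	N
L	N	D
S	N	D
P	T	D
L	P	D
S	S	N
P	N	N
L	N	D
S	T	D
P2	T	N
L2	N	N
S2	N	D
E1	G	D
E2	S	T
DYW	-	-
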