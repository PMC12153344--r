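pair	A	C	G	U
TN	1	-0.25	0.25	0
ND	-0.25	0.25	0	1
TD	0	-0.25	1	0.25
PD	0.25	0	-0.5	1
SN	1	0.5	-0.25	0
NN	0.25	1	-0.25	0.5
NS	0	1	0.25	-0.25
GD	0.5	0	-0.25	0.25
ST	0.25	-0.25	0	0.5
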