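A	C	G	T
-1.14	1.37	-0.21	-1.58
0.62	-1.10	0.17	-0.50
-1.58	0.73	0.48	-1.58
1.32	0.33	-1.58	-1.13
-1.58	0.94	0.33	-1.58
-1.58	-1.58	0.99	-1.13
0.62	-1.14	-0.11	0.27
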