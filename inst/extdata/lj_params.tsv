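element	sigma	epsilon
H	2.42	0.030
C	3.55	0.070
N	3.25	0.170
O	3.00	0.210
S	3.60	0.250
P	3.74	0.200
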