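resName	name	charge
ASP	OD1	-0.5
ASP	OD2	-0.5
GLU	OE1	-0.5
GLU	OE2	-0.5
LYS	NZ	1.0
ARG	NH1	0.5
ARG	NH2	0.5
HIP	ND1	0.5
HIP	NE2	0.5
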