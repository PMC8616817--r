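type	atom_a	atom_b	elem_a	elem_b	r	scale
NH	N	H	N	H	1.020	1.000000
CAHA	CA	HA	C	H	1.090	-2.032300
CAC	CA	C	C	C	1.525	-0.186640
CN	C	N	C	N	1.329	0.113688
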