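resname	atom	shift
ALA	H	8.24
ALA	N	123.8
ALA	CA	52.5
ALA	HA	4.32
ALA	CB	19.1
ALA	HB1	1.39
ALA	HB2	1.39
ALA	HB3	1.39
ARG	H	8.23
ARG	N	120.5
ARG	CA	56
ARG	HA	4.34
ARG	CB	30.9
ARG	HB2	1.86
ARG	HB3	1.76
ARG	CG	27
ARG	HG2	1.63
ARG	HG3	1.54
ARG	CD	43.2
ARG	HD2	3.2
ARG	HD3	3.17
ARG	NE	84.7
ARG	HE	7.17
ASN	H	8.4
ASN	N	118.7
ASN	CA	53.1
ASN	HA	4.74
ASN	CB	38.9
ASN	HB2	2.83
ASN	HB3	2.75
ASN	ND2	112.8
ASN	HD21	7.59
ASN	HD22	6.91
ASP	H	8.34
ASP	N	120.4
ASP	CA	54.2
ASP	HA	4.64
ASP	CB	41.1
ASP	HB2	2.72
ASP	HB3	2.65
CYS	H	8.32
CYS	N	118.8
CYS	CA	58.2
CYS	HA	4.55
CYS	CB	28
CYS	HB2	2.95
CYS	HB3	2.88
GLN	H	8.32
GLN	N	119.8
GLN	CA	55.7
GLN	HA	4.34
GLN	CB	29.4
GLN	HB2	2.12
GLN	HB3	1.99
GLN	CG	33.8
GLN	HG2	2.36
GLN	HG3	2.32
GLN	NE2	111.9
GLN	HE21	7.52
GLN	HE22	6.85
GLU	H	8.42
GLU	N	120.2
GLU	CA	56.6
GLU	HA	4.35
GLU	CB	29.9
GLU	HB2	2.06
GLU	HB3	1.96
GLU	CG	36.1
GLU	HG2	2.31
GLU	HG3	2.28
GLY	H	8.33
GLY	N	108.8
GLY	CA	45.1
GLY	HA2	3.96
GLY	HA3	3.9
HIS	H	8.42
HIS	N	118.2
HIS	CA	55
HIS	HA	4.73
HIS	CB	29
HIS	HB2	3.26
HIS	HB3	3.15
HIS	CD2	119.8
HIS	HD2	7.09
HIS	CE1	136.4
HIS	HE1	8.12
ILE	H	8
ILE	N	120.6
ILE	CA	61.1
ILE	HA	4.17
ILE	CB	38.8
ILE	HB	1.87
ILE	CG1	27.7
ILE	HG12	1.45
ILE	HG13	1.16
ILE	CG2	17.4
ILE	HG21	0.91
ILE	HG22	0.91
ILE	HG23	0.91
ILE	CD1	13.5
ILE	HD11	0.87
ILE	HD12	0.87
ILE	HD13	0.87
LEU	H	8.16
LEU	N	121.8
LEU	CA	55.1
LEU	HA	4.34
LEU	CB	42.4
LEU	HB2	1.62
LEU	HB3	1.58
LEU	CG	26.8
LEU	HG	1.59
LEU	CD1	24.7
LEU	HD11	0.92
LEU	HD12	0.92
LEU	HD13	0.92
LEU	CD2	23.8
LEU	HD21	0.87
LEU	HD22	0.87
LEU	HD23	0.87
LYS	H	8.29
LYS	N	121
LYS	CA	56.2
LYS	HA	4.32
LYS	CB	33.1
LYS	HB2	1.84
LYS	HB3	1.75
LYS	CG	24.9
LYS	HG2	1.44
LYS	HG3	1.41
LYS	CD	29
LYS	HD2	1.68
LYS	HD3	1.66
LYS	CE	42
LYS	HE2	2.99
LYS	HE3	2.97
MET	H	8.28
MET	N	119.6
MET	CA	55.4
MET	HA	4.48
MET	CB	32.9
MET	HB2	2.11
MET	HB3	2.01
MET	CG	32
MET	HG2	2.6
MET	HG3	2.54
MET	CE	16.9
MET	HE1	2.1
MET	HE2	2.1
MET	HE3	2.1
PHE	H	8.3
PHE	N	120.3
PHE	CA	57.7
PHE	HA	4.62
PHE	CB	39.6
PHE	HB2	3.14
PHE	HB3	3.04
PHE	CD1	131.5
PHE	CD2	131.5
PHE	HD1	7.28
PHE	HD2	7.28
PHE	CE1	130.8
PHE	CE2	130.8
PHE	HE1	7.38
PHE	HE2	7.38
PHE	CZ	129.5
PHE	HZ	7.32
PRO	N	137
PRO	CA	63.3
PRO	HA	4.42
PRO	CB	32.1
PRO	HB2	2.28
PRO	HB3	1.95
PRO	CG	27.2
PRO	HG2	2.02
PRO	HG3	1.97
PRO	CD	50.3
PRO	HD2	3.68
PRO	HD3	3.63
SER	H	8.35
SER	N	116.6
SER	CA	58.3
SER	HA	4.47
SER	CB	63.8
SER	HB2	3.88
SER	HB3	3.85
THR	H	8.15
THR	N	114
THR	CA	61.8
THR	HA	4.35
THR	CB	69.8
THR	HB	4.24
THR	CG2	21.5
THR	HG21	1.21
THR	HG22	1.21
THR	HG23	1.21
TRP	H	8.11
TRP	N	121.3
TRP	CA	57.5
TRP	HA	4.66
TRP	CB	29.6
TRP	HB2	3.29
TRP	HB3	3.27
TRP	CD1	127
TRP	HD1	7.24
TRP	NE1	129.4
TRP	HE1	10.09
TRP	CE3	120.5
TRP	HE3	7.64
TRP	CZ2	114.5
TRP	HZ2	7.49
TRP	CZ3	121.5
TRP	HZ3	7.15
TRP	CH2	123.8
TRP	HH2	7.23
TYR	H	8.18
TYR	N	120.8
TYR	CA	57.9
TYR	HA	4.55
TYR	CB	38.8
TYR	HB2	3.05
TYR	HB3	2.98
TYR	CD1	132.8
TYR	CD2	132.8
TYR	HD1	7.14
TYR	HD2	7.14
TYR	CE1	118
TYR	CE2	118
TYR	HE1	6.84
TYR	HE2	6.84
VAL	H	8.19
VAL	N	121.1
VAL	CA	62.2
VAL	HA	4.12
VAL	CB	32.9
VAL	HB	2.08
VAL	CG1	21.1
VAL	HG11	0.94
VAL	HG12	0.94
VAL	HG13	0.94
VAL	CG2	20.3
VAL	HG21	0.92
VAL	HG22	0.92
VAL	HG23	0.92
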