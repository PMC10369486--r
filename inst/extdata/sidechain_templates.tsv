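aa	atom	a	b	c	length	angle	chi	offset
ARG	CG	N	CA	CB	1.52	114	1	0
ARG	CD	CA	CB	CG	1.52	111	2	0
ARG	NE	CB	CG	CD	1.46	112	3	0
ARG	CZ	CG	CD	NE	1.33	124	4	0
ARG	NH1	CD	NE	CZ	1.33	120	NA	0
ARG	NH2	CD	NE	CZ	1.33	120	NA	180
ASN	CG	N	CA	CB	1.52	112	1	0
ASN	OD1	CA	CB	CG	1.23	120	2	0
ASN	ND2	CA	CB	CG	1.33	116	2	180
ASP	CG	N	CA	CB	1.52	112	1	0
ASP	OD1	CA	CB	CG	1.25	118	2	0
ASP	OD2	CA	CB	CG	1.25	118	2	180
CYS	SG	N	CA	CB	1.81	114	1	0
GLN	CG	N	CA	CB	1.52	114	1	0
GLN	CD	CA	CB	CG	1.52	111	2	0
GLN	OE1	CB	CG	CD	1.23	120	3	0
GLN	NE2	CB	CG	CD	1.33	116	3	180
GLU	CG	N	CA	CB	1.52	114	1	0
GLU	CD	CA	CB	CG	1.52	111	2	0
GLU	OE1	CB	CG	CD	1.25	118	3	0
GLU	OE2	CB	CG	CD	1.25	118	3	180
HIS	CG	N	CA	CB	1.5	114	1	0
HIS	ND1	CA	CB	CG	1.38	122	2	0
HIS	CD2	CA	CB	CG	1.36	129	2	180
HIS	CE1	CB	CG	ND1	1.32	109	NA	180
HIS	NE2	CG	ND1	CE1	1.32	108	NA	0
ILE	CG1	N	CA	CB	1.53	110	1	0
ILE	CG2	N	CA	CB	1.53	110	1	-122
ILE	CD1	CA	CB	CG1	1.52	114	2	0
LEU	CG	N	CA	CB	1.53	116	1	0
LEU	CD1	CA	CB	CG	1.52	110	2	0
LEU	CD2	CA	CB	CG	1.52	110	2	122
LYS	CG	N	CA	CB	1.52	114	1	0
LYS	CD	CA	CB	CG	1.52	111	2	0
LYS	CE	CB	CG	CD	1.52	111	3	0
LYS	NZ	CG	CD	CE	1.49	112	4	0
MET	CG	N	CA	CB	1.52	114	1	0
MET	SD	CA	CB	CG	1.81	112	2	0
MET	CE	CB	CG	SD	1.79	100	3	0
PHE	CG	N	CA	CB	1.5	114	1	0
PHE	CD1	CA	CB	CG	1.39	120	2	0
PHE	CD2	CA	CB	CG	1.39	120	2	180
PHE	CE1	CB	CG	CD1	1.39	120	NA	180
PHE	CE2	CB	CG	CD2	1.39	120	NA	180
PHE	CZ	CG	CD1	CE1	1.39	120	NA	0
PRO	CG	N	CA	CB	1.5	104	1	0
PRO	CD	CA	CB	CG	1.5	105	2	0
SER	OG	N	CA	CB	1.42	111	1	0
THR	OG1	N	CA	CB	1.43	109	1	0
THR	CG2	N	CA	CB	1.52	110	1	-120
TRP	CG	N	CA	CB	1.5	114	1	0
TRP	CD1	CA	CB	CG	1.37	127	2	0
TRP	CD2	CA	CB	CG	1.43	126	2	180
TRP	NE1	CB	CG	CD1	1.38	110	NA	180
TRP	CE2	CB	CG	CD2	1.4	107	NA	180
TYR	CG	N	CA	CB	1.5	114	1	0
TYR	CD1	CA	CB	CG	1.39	120	2	0
TYR	CD2	CA	CB	CG	1.39	120	2	180
TYR	CE1	CB	CG	CD1	1.39	120	NA	180
TYR	CE2	CB	CG	CD2	1.39	120	NA	180
TYR	CZ	CG	CD1	CE1	1.39	120	NA	0
TYR	OH	CD1	CE1	CZ	1.38	120	NA	180
VAL	CG1	N	CA	CB	1.53	110	1	0
VAL	CG2	N	CA	CB	1.53	110	1	122
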