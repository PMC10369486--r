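aa	chi	a1	a2	a3	a4	symmetric
ARG	1	N	CA	CB	CG	FALSE
ARG	2	CA	CB	CG	CD	FALSE
ARG	3	CB	CG	CD	NE	FALSE
ARG	4	CG	CD	NE	CZ	FALSE
ASN	1	N	CA	CB	CG	FALSE
ASN	2	CA	CB	CG	OD1	FALSE
ASP	1	N	CA	CB	CG	FALSE
ASP	2	CA	CB	CG	OD1	TRUE
CYS	1	N	CA	CB	SG	FALSE
GLN	1	N	CA	CB	CG	FALSE
GLN	2	CA	CB	CG	CD	FALSE
GLN	3	CB	CG	CD	OE1	FALSE
GLU	1	N	CA	CB	CG	FALSE
GLU	2	CA	CB	CG	CD	FALSE
GLU	3	CB	CG	CD	OE1	TRUE
HIS	1	N	CA	CB	CG	FALSE
HIS	2	CA	CB	CG	ND1	FALSE
ILE	1	N	CA	CB	CG1	FALSE
ILE	2	CA	CB	CG1	CD1	FALSE
LEU	1	N	CA	CB	CG	FALSE
LEU	2	CA	CB	CG	CD1	FALSE
LYS	1	N	CA	CB	CG	FALSE
LYS	2	CA	CB	CG	CD	FALSE
LYS	3	CB	CG	CD	CE	FALSE
LYS	4	CG	CD	CE	NZ	FALSE
MET	1	N	CA	CB	CG	FALSE
MET	2	CA	CB	CG	SD	FALSE
MET	3	CB	CG	SD	CE	FALSE
PHE	1	N	CA	CB	CG	FALSE
PHE	2	CA	CB	CG	CD1	TRUE
PRO	1	N	CA	CB	CG	FALSE
PRO	2	CA	CB	CG	CD	FALSE
SER	1	N	CA	CB	OG	FALSE
THR	1	N	CA	CB	OG1	FALSE
TRP	1	N	CA	CB	CG	FALSE
TRP	2	CA	CB	CG	CD1	FALSE
TYR	1	N	CA	CB	CG	FALSE
TYR	2	CA	CB	CG	CD1	TRUE
VAL	1	N	CA	CB	CG1	FALSE
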