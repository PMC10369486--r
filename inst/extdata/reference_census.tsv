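aa	canonical	off	total
ALA	NA	NA	48429
ARG	11829	9347	21176
ASN	19398	2062	21460
ASP	29155	718	29873
CYS	6562	44	6606
GLN	12926	3264	16190
GLU	24918	1472	26390
GLY	NA	NA	42216
HIS	12059	553	12612
ILE	30857	452	31309
LEU	49462	2334	51796
LYS	17941	2920	20861
MET	6335	905	7240
PHE	22807	521	23328
PRO	23159	2646	25805
SER	28972	283	29255
THR	29334	170	29504
TRP	7896	469	8365
TYR	20155	497	20652
VAL	39791	166	39957
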