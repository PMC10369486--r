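aa	label	mode1	mode2	mode3	mode4	weight
CYS	m	-65	NA	NA	NA	3674
CYS	p	65	NA	NA	NA	1102
CYS	t	180	NA	NA	NA	1786
CYS	off	NA	NA	NA	NA	44
SER	m	-65	NA	NA	NA	8143
SER	p	65	NA	NA	NA	14059
SER	t	180	NA	NA	NA	6770
SER	off	NA	NA	NA	NA	283
THR	m	-65	NA	NA	NA	12932
THR	p	65	NA	NA	NA	14256
THR	t	180	NA	NA	NA	2146
THR	off	NA	NA	NA	NA	170
VAL	m	-65	NA	NA	NA	7475
VAL	p	65	NA	NA	NA	2664
VAL	t	180	NA	NA	NA	29652
VAL	off	NA	NA	NA	NA	166
ASN	m-20	-65	-20	NA	NA	7003
ASN	m-80	-65	-80	NA	NA	2021
ASN	m120	-65	120	NA	NA	2120
ASN	p-10	65	-10	NA	NA	1194
ASN	p30	65	30	NA	NA	1548
ASN	t-20	180	-20	NA	NA	2704
ASN	t30	180	30	NA	NA	2808
ASN	off	NA	NA	NA	NA	2062
ASP	m-20	-65	-20	NA	NA	14654
ASP	p-10	65	-10	NA	NA	2537
ASP	p30	65	30	NA	NA	2521
ASP	t0	180	0	NA	NA	6885
ASP	t70	180	70	NA	NA	2558
ASP	off	NA	NA	NA	NA	718
HIS	m-70	-65	-70	NA	NA	3647
HIS	m170	-65	170	NA	NA	1097
HIS	m80	-65	80	NA	NA	1710
HIS	p-80	65	-80	NA	NA	857
HIS	p80	65	80	NA	NA	609
HIS	t-160	180	-160	NA	NA	528
HIS	t-80	180	-80	NA	NA	3611
HIS	off	NA	NA	NA	NA	553
ILE	mm	-65	-65	NA	NA	4979
ILE	mp	-65	65	NA	NA	335
ILE	mt	-65	180	NA	NA	18837
ILE	pp	65	65	NA	NA	167
ILE	pt	65	180	NA	NA	3897
ILE	tp	180	65	NA	NA	831
ILE	tt	180	180	NA	NA	1811
ILE	off	NA	NA	NA	NA	452
LEU	mp	-65	65	NA	NA	1278
LEU	mt	-65	180	NA	NA	31694
LEU	pp	65	65	NA	NA	374
LEU	tp	180	65	NA	NA	15053
LEU	tt	180	180	NA	NA	1063
LEU	off	NA	NA	NA	NA	2334
PHE	m-30	-65	-30	NA	NA	2047
PHE	m-85	-65	-85	NA	NA	10655
PHE	p90	65	90	NA	NA	2542
PHE	t80	180	80	NA	NA	7563
PHE	off	NA	NA	NA	NA	521
PRO	Cg endo	30	NA	NA	NA	11230
PRO	Cg exo	-30	NA	NA	NA	11929
PRO	off	NA	NA	NA	NA	2646
TRP	m-90	-65	-90	NA	NA	409
TRP	m0	-65	0	NA	NA	791
TRP	m95	-65	95	NA	NA	2654
TRP	p-90	65	-90	NA	NA	812
TRP	p90	65	90	NA	NA	390
TRP	t-105	180	-105	NA	NA	2840
TRP	off	NA	NA	NA	NA	469
TYR	m-30	-65	-30	NA	NA	1577
TYR	m-85	-65	-85	NA	NA	9384
TYR	p90	65	90	NA	NA	2340
TYR	t80	180	80	NA	NA	6854
TYR	off	NA	NA	NA	NA	497
GLN	mm-40	-65	-65	-40	NA	1986
GLN	mm100	-65	-65	100	NA	799
GLN	mp0	-65	65	0	NA	428
GLN	mt-30	-65	180	-30	NA	4975
GLN	pm0	65	-65	0	NA	170
GLN	pt20	65	180	20	NA	606
GLN	tp-100	180	65	-100	NA	372
GLN	tp60	180	65	60	NA	1205
GLN	tt0	180	180	0	NA	2385
GLN	off	NA	NA	NA	NA	3264
GLU	mm-40	-65	-65	-40	NA	3843
GLU	mp0	-65	65	0	NA	1572
GLU	mt-10	-65	180	-10	NA	9296
GLU	pm0	65	-65	0	NA	597
GLU	pt-20	65	180	-20	NA	1353
GLU	tm-20	180	-65	-20	NA	319
GLU	tp10	180	65	10	NA	1850
GLU	tt0	180	180	0	NA	6088
GLU	off	NA	NA	NA	NA	1472
MET	mmm	-65	-65	-65	NA	1302
MET	mmp	-65	-65	65	NA	282
MET	mmt	-65	-65	180	NA	232
MET	mtm	-65	180	-65	NA	774
MET	mtp	-65	180	65	NA	1179
MET	mtt	-65	180	180	NA	566
MET	ptm	65	180	-65	NA	176
MET	ptp	65	180	65	NA	160
MET	tpp	180	65	65	NA	427
MET	tpt	180	65	180	NA	84
MET	ttm	180	180	-65	NA	433
MET	ttp	180	180	65	NA	504
MET	ttt	180	180	180	NA	216
MET	off	NA	NA	NA	NA	905
ARG	mmm-85	-65	-65	-65	-85	463
ARG	mmm180	-65	-65	-65	180	313
ARG	mmt-85	-65	-65	180	-85	567
ARG	mmt180	-65	-65	180	180	500
ARG	mmt85	-65	-65	180	85	244
ARG	mtm-85	-65	180	-65	-85	1207
ARG	mtm105	-65	180	-65	105	316
ARG	mtm180	-65	180	-65	180	1005
ARG	mtp-105	-65	180	65	-105	254
ARG	mtp180	-65	180	65	180	958
ARG	mtp85	-65	180	65	85	775
ARG	mtt-85	-65	180	180	-85	1150
ARG	mtt180	-65	180	180	180	1731
ARG	mtt85	-65	180	180	85	922
ARG	ptm-85	65	180	-65	-85	72
ARG	ptm180	65	180	-65	180	146
ARG	ptp180	65	180	65	180	184
ARG	ptp85	65	180	65	85	100
ARG	ptt-85	65	180	180	-85	282
ARG	ptt180	65	180	180	180	303
ARG	ptt85	65	180	180	85	337
ARG	off	NA	NA	NA	NA	9347
LYS	mmmt	-65	-65	-65	180	309
LYS	mmtm	-65	-65	180	-65	433
LYS	mmtp	-65	-65	180	65	289
LYS	mmtt	-65	-65	180	180	1532
LYS	mptt	-65	65	180	180	65
LYS	mtmm	-65	180	-65	-65	250
LYS	mtmt	-65	180	-65	180	724
LYS	mtpp	-65	180	65	65	239
LYS	mtpt	-65	180	65	180	736
LYS	mttm	-65	180	180	-65	1058
LYS	mttp	-65	180	180	65	800
LYS	mttt	-65	180	180	180	4358
LYS	ptmt	65	180	-65	180	104
LYS	ptpt	65	180	65	180	95
LYS	pttm	65	180	180	-65	145
LYS	pttp	65	180	180	65	149
LYS	pttt	65	180	180	180	694
LYS	tptm	180	65	180	-65	124
LYS	tptp	180	65	180	65	190
LYS	tptt	180	65	180	180	544
LYS	ttmm	180	180	-65	-65	123
LYS	ttmt	180	180	-65	180	385
LYS	ttpp	180	180	65	65	148
LYS	ttpt	180	180	65	180	475
LYS	tttm	180	180	180	-65	719
LYS	tttp	180	180	180	65	686
LYS	tttt	180	180	180	180	2567
LYS	off	NA	NA	NA	NA	2920
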