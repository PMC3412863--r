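1	600000	720000	CD46(MCP)
1	1200000	1320000	LGR6
1	1800000	1920000	OBSCN
1	2400000	2520000	PTPRU
2	600000	720000	LRP2
2	1200000	1320000	MAP2
3	600000	720000	CHL1
3	1200000	1320000	CNTN4
3	1800000	1920000	EPHA3
3	2400000	2520000	P2RY14
3	3000000	3120000	TGFBR2
3	3600000	3720000	TTLL3
4	600000	720000	ADAM29
4	1200000	1320000	FBXW7
5	600000	720000	APC
5	1200000	1320000	HAPLN1
6	600000	720000	CD109
6	1200000	1320000	EYA4
6	1800000	1920000	HIST1H1B
6	2400000	2520000	KCNQ5
6	3000000	3120000	PHIP
6	3600000	3720000	PKHD1
6	4200000	4320000	SLC29A1
6	4800000	4920000	SLC44A4(C6orf29)
6	5400000	5520000	SYNE1
7	600000	720000	EPHB6
7	1200000	1320000	EXOC4(SEC8L1)
7	1800000	1920000	MLL3
8	600000	720000	CSMD3
8	1200000	1320000	RUNX1T1
9	600000	720000	ABCA1
9	1200000	1320000	PTPRD
9	1800000	1920000	UHRF2
10	600000	720000	ACSL5
10	1200000	1320000	C10orf137
10	1800000	1920000	ERCC6
10	2400000	2520000	RET
10	3000000	3120000	TCF7L2
11	600000	720000	ADAMTS15
11	1200000	1320000	CD248
11	1800000	1920000	GUCY1A2
11	2400000	2520000	SCN3B
12	600000	720000	KRAS
12	1200000	1320000	KRT73(K6IRS3)
12	1800000	1920000	P2RX7
13	600000	720000	LMO7
14	600000	720000	EVL
14	1200000	1320000	KIAA1409
14	1800000	1920000	PRKD1
15	600000	720000	ADAMTSL3
15	1200000	1320000	C15orf2
15	1800000	1920000	MKRN3
15	2400000	2520000	SMAD3
16	600000	720000	ADAMTS18
16	1200000	1320000	GALNS
16	1800000	1920000	MMP2
16	2400000	2520000	UQCRC2
17	600000	720000	NF1
17	1200000	1320000	TP53
18	600000	720000	SMAD2
18	1200000	1320000	SMAD4
19	600000	720000	ACTL9
19	1200000	1320000	ZNF442
20	600000	720000	ERGIC3(SBDCAG84)
20	1200000	1320000	GNAS
20	1800000	1920000	SFRS6
21	600000	720000	PKNOX1
X	600000	720000	TBX22
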