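symbol,cytoband,amplified_count,amplified_percent,deleted_count,deleted_percent
ABCA1,9q31.1,1,3,1,3
ACSL5,10q25,1,3,5,16
ADAM29,4q34,0,0,8,26
ADAMTS15,11q25,3,10,3,10
ADAMTS18,16q23,11,36,1,3
ADAMTSL3,15q25.2,1,3,6,20
APC,5q22,2,6,8,26
C10orf137,10q26.1,1,3,4,13
C15orf2,15q11,0,0,7,23
CD109,6q13,8,26,1,3
CD248,11q13,11,36,3,10
CD46(MCP),1q32,4,13,3,10
CHL1,3p26.1,2,6,1,3
CNTN4,3p26,4,13,1,3
CSMD3,8q23.3,14,46,2,6
EPHA3,3p11.2,3,10,1,3
EPHB6,7q34,18,60,0,0
ERCC6,10q11.2,3,10,2,6
ERGIC3(SBDCAG84),20q12,20,66,0,0
EVL,14q32.2,4,13,5,16
EXOC4(SEC8L1),7q31,18,60,0,0
EYA4,6q23,4,13,2,6
FBXW7,4q31.3,0,0,8,26
GALNS,16q24.3,14,46,1,3
GNAS,20q13.3,19,63,0,0
GUCY1A2,11q22,3,10,6,20
HAPLN1,5q14.3,1,3,9,30
HIST1H1B,6p22,11,36,0,0
KCNQ5,6q14,9,30,1,3
KIAA1409,14q32.1,5,16,2,6
KRAS,12p12.1,8,26,1,3
KRT73(K6IRS3),12q13.3,11,36,0,0
LGR6,1q32.1,4,13,3,10
LMO7,13q22.2,17,56,1,3
LRP2,2q31,6,20,2,6
MAP2,2q34-35,6,20,2,6
ACTL9,19p13.2,NA,NA,NA,NA
MKRN3,15q11,0,0,5,16
MLL3,7q36.1,16,53,0,0
MMP2,16q12-13,15,50,1,3
NF1,17q11.2,12,40,8,26
OBSCN,1q42.1,4,13,3,10
P2RX7,12q24,8,26,1,3
P2RY14,3q25,6,20,1,3
PHIP,6q14,8,26,1,3
PKHD1,6p12.2,5,16,1,3
PKNOX1,21q22.3,7,23,7,23
PRKD1,14q11,2,6,6,20
PTPRD,9p23-24,1,3,1,3
PTPRU,1p35,6,20,6,20
RET,10q11.2,0,NA,2,6
RUNX1T1,8q22,14,46,2,6
SCN3B,11q23.3,3,10,3,10
SFRS6,20q13.1,19,63,0,NA
SLC29A1,6p21,11,36,2,6
SLC44A4(C6orf29),6p21.3,11,36,2,6
SMAD2,18q21.1,0,NA,16,53
SMAD3,15q22.3,1,3,6,20
SMAD4,18q21.1,0,NA,16,53
SYNE1,6q25,4,13,2,6
TBX22,Xq21.1,12,40,4,13
TCF7L2,10q25.3,1,3,5,16
TGFBR2,3p22,4,13,1,3
TP53,17p13.1,10,33,10,33
TTLL3,3p25.3,5,16,2,6
UHRF2,9p24.1,1,3,1,3
UQCRC2,16p12,10,33,1,3
ZNF442,19p13.2,12,40,7,23
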