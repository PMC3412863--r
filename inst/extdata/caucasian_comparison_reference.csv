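symbol,cytoband,caucasian_amplified_percent,caucasian_deleted_percent,aa_amplified_percent,aa_deleted_percent
THRB,3p24.3,NA,32,13,3
RAF1,3p25,NA,14,20,6
RFC2,7q11.2,36,NA,60,3
CYLN2,7q11.23,36,NA,NA,NA
MET,7q31,23,NA,60,0
LPL,8p22,NA,23,10,40
E2F5,8q22-q21.3,36,NA,53,0
LPL,8p22,NA,23,NA,NA
EXT1,8q24.11-q24.13,32,NA,46,6
MYC,8q24.12-q24.13,36,NA,46,0
EGR2,10q21.3,NA,23,10,13
DMBT1,10q25.3-q26.1,NA,23,3,16
LRRC32,11q13.5,32,NA,10,13
ATM,11q22.3,27,NA,10,16
INS,11ptel,32,NA,26,6
BRCA2,13q12-q13,36,NA,60,0
RB1,13q14,41,NA,53,0
MAP2K5,15q23,NA,32,3,20
SP6,17ptel,NA,23,30,30
TOP3A,17p11.2,NA,NA,10,33
LLGL1,17p12-17p11.2,NA,36,10,33
FLII,17p12-17p11.2,NA,23,10,33
HIC1,17p13.3,NA,32,20,30
CTDP1,18qtel,NA,45,0,40
LAMA3,18q11.2,NA,14,0,40
BCL2,18q21.3,NA,23,0,40
DCC,18q21.3,32,18,0,50
TPD52L2,20qtel,27,NA,76,3
TOP1,20q12-q13.1,32,NA,56,0
TNFRSF6B,20q13,32,NA,53,3
NCOA3,20q13,32,NA,63,0
AURKA,20q13,36,NA,56,0
CSE1L,20q13,27,NA,63,0
MYBL2,20q13.1,32,NA,63,0
PTPN1,20q13.1-q13.2,23,NA,63,0
CYP24A1,20q13.2,36,NA,63,0
ZNF217,20q13.2,32,NA,63,0
PRPF6,20q13.3,27,NA,60,3
PCNT,21qtel,NA,18,16,20
XIST,Xq13.2,36,NA,33,13
STS,Xp22.3,NA,23,23,13
KAL1,Xp22.3,36,NA,30,13
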