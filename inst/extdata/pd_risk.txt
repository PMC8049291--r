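ADRA2A
ASXL3
BAG3
BIN3
BRIP1
BST1
C5orf24
CAB39L
CAMK2D
CASC16
CD19
CHD9
CHRNB1
CLCN3
CRHR1
CRLS1
CTSB
DLG2
DNAH17
DYRK1A
ELOVL7
FAM171A2
FAM47E
FAM49B
FBRSL1
FCGR2A
FGF20
FYN
GAK
GALC
GBAP1
GBF1
GCH1
GPNMB
GS1-124K5.11
HIP1R
HLA-DRB5
IGSF9B
INPP5F
IP6K2
ITGA8
ITPKB
KCNIP3
KCNS3
KPNA1
KRTCAP2
LCORL
LINC00693
LOC100131289
LRRK2
MAP4K4
MBNL2
MCCC1
MED12L
MEX3C
MIPOL1
NOD2
NUCKS1
PAM
PMVK
RAB29
RETREG3
RIMS1
RIT2
RNF141
RPS12
RPS6KL1
SATB1
SCAF11
SCARB2
SETD1A
SH3GL2
SIPA1L2
SLC44A1
SNCA
SPPL2B
SPTSSB
STK39
SV2C
SYT17
TMEM163
TMEM175
TRIM40
UBAP2
UBTF
VAMP4
VPS13C
WBSCR17
WNT3
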