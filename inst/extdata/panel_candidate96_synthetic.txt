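# Candidate gene panel for vertebral segmentation defects (96 genes).
# SYNTHETIC STAND-IN: the 21 study-named genes plus 75 plausible
# somitogenesis/vertebral-development genes padding to 96.
BAZ1B
FREM2
SUFU
VANGL1
KMT2D
MYO18B
GDF6
MEOX1
GDF3
RIPPLY2
GRIP1
TBX6
WNT7A
FUZ
MAP3K7
POR
CHD7
FRAS1
COG1
ANKRD11
HOXD13
DLL3
MESP2
LFNG
HES7
TBX1
TBXT
DLL1
DLL4
NOTCH1
NOTCH2
JAG1
JAG2
PAX1
PAX9
SHH
GLI2
GLI3
PTCH1
WNT3A
WNT5A
CDX1
CDX2
CDX4
FGF8
FGF4
FGFR1
FGFR2
FGFR3
RARB
RARG
ALDH1A2
CYP26A1
CYP26B1
RIPPLY1
MESP1
HES1
HES5
HEY1
HEY2
SOX9
RUNX2
NOG
BMP2
BMP4
BMP7
GDF11
ACVR2B
TGFB2
SMAD3
SMAD6
LTBP3
TBX15
TBX18
UNCX
MEOX2
PCDH8
PSEN1
RBPJ
MAML1
NRARP
EPHA4
EFNB2
ITGA5
FN1
TCF15
MYF5
PAX3
SIX1
EYA1
FOXC1
FOXC2
ZIC1
ZIC4
SLC35A3
DUSP6
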