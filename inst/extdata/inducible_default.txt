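# Literature reprogramming factors: Yamanaka factors and published substitutes
# (c-Myc: MYCL, MYCN, GLIS1; Klf4: KLF1, KLF2, KLF5, ESRRB, BMP4;
#  Sox2: RCOR2, GMNN, TH2A, TH2B, OBOX1, SOX1, SOX3;
#  Oct4: NR5A1, NR5A2, CDH1, TCL1A, POU3F4, TET1)
POU5F1
SOX2
KLF4
MYC
MYCL
MYCN
GLIS1
KLF1
KLF2
KLF5
ESRRB
BMP4
RCOR2
GMNN
TH2A
TH2B
OBOX1
SOX1
SOX3
NR5A1
NR5A2
CDH1
TCL1A
POU3F4
TET1
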