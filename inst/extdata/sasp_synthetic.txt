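IL6
IL1A
IL1B
CXCL8
CXCL1
CXCL2
CCL2
CCL20
MMP1
MMP3
MMP12
IGFBP3
ICAM1
TNFRSF1B
PLAUR
TIMP1
HGF
FGF2
VEGFA
SERPINE2
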