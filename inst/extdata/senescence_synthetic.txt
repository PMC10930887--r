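CDKN1A
CDKN2A
TP53
GLB1
SERPINE1
LMNB1
MKI67
CCND1
E2F1
FOXO4
TRP53BP1
HMGB1
IGFBP5
PLAU
TIMP2
MAP2K3
GADD45A
ZFP36L1
CITED2
BHLHE40
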