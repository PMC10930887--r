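MT1X
MT2A
RPL36A
EEF1A2
CYP1B1
ID3
NR4A1
EGR1
FOS
JUNB
KLF2
DUSP1
SOCS3
ZFP36
GADD45B
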