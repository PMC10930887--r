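VEGFA
SLC2A1
PGK1
LDHA
CA9
NDRG1
ADM
ANKRD37
BNIP3
PDK1
EGLN3
DDIT4
ENO2
P4HA1
AK4
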