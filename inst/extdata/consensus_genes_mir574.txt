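ACVR1B
BACE1
CCDC39
CLTC
CSDC2
CUL2
DAB2IP
DCP1A
EP300
EPHA8
FBXL5
FOSL2
MESDC1
NDUFA4L2
POFUT2
RXRA
SAMD4A
SNRK
TMCC1
TMEM181
TMPRSS11D
USP45
WDR82
ZBTB5
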