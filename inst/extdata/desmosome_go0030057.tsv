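gene_symbol
DSP
PPL
EVPL
PERP
PNN
JUP
PKP1
PKP2
PKP3
PKP4
DSG1
DSG2
DSG3
DSG4
DSC1
DSC2
DSC3
CTNND1
CDH1
KAZN
DST
MACF1
EPPK1
KRT5
KRT14
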