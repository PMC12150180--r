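BRCA1
BRCA2
PALB2
RAD51C
RAD51D
BRIP1
BARD1
PTEN
CDH1
STK11
TP53
CHEK2
ATM
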