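APOB
ATP7B
GLA
HFE
KCNH2
LDLR
MLH1
MSH2
MSH6
MUTYH
MYBPC3
MYH7
PMS2
RET
SDHB
SDHD
TSC1
TSC2
TTN
VHL
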