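node,expression
BRAF,"max(var(RAS), var(BRAF_V600E))"
Ets1,"2 * floor(var(ERK) / 2)"
Sp1,"2"
JNK,"max(var(TNFR_M), var(Wnt5a))"
cJUN,"max(var(JNK), 2 - var(MITF))"
TNF,"min(var(Sp1), var(Ets1), var(cJUN))"
TNFR_M,"min(2, 2 * var(TNF))"
IKK,"max(var(TNFR_M), var(AKT))"
PI3K,"var(RTK) + (2 - var(PTEN)) / 2"
MDM2,"2"
CDK4,"var(CyclinD) - avg(var(CDKN2A), var(p21))"
Proliferation,"min(var(E2F), avg(var(NFkB), var(AKT)))"
Apoptosis,"max(var(p53), 2 - var(NFkB) - var(AKT))"
Residency_LC,"var(Id2_LC) - var(TNFR_LC) / 2 - var(KC_signal) / 2"
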