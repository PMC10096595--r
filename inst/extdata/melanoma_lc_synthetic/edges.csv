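source,target,sign
GF,RTK,activating
RTK,RAS,activating
RAS,BRAF,activating
BRAF_V600E,BRAF,activating
BRAF,MEK,activating
MEK,ERK,activating
ERK,Ets1,activating
TNFR_M,JNK,activating
Wnt5a,JNK,activating
JNK,cJUN,activating
MITF,cJUN,inhibiting
Sp1,TNF,activating
Ets1,TNF,activating
cJUN,TNF,activating
TNF,TNFR_M,activating
TNFR_M,IKK,activating
AKT,IKK,activating
IKK,NFkB,activating
RTK,PI3K,activating
PTEN,PI3K,inhibiting
PI3K,AKT,activating
MDM2,p53,inhibiting
p53,p21,activating
ERK,CyclinD,activating
CyclinD,CDK4,activating
CDKN2A,CDK4,inhibiting
p21,CDK4,inhibiting
CDK4,E2F,activating
E2F,Proliferation,activating
NFkB,Proliferation,activating
AKT,Proliferation,activating
p53,Apoptosis,activating
NFkB,Apoptosis,inhibiting
AKT,Apoptosis,inhibiting
TGFB,TBR_LC,activating
TBR_LC,SMAD3_LC,activating
SMAD3_LC,Id2_LC,activating
TNF,TNFR_LC,activating
IL1B,IL1R_KC,activating
IL1R_KC,KC_signal,activating
GF_LC,PI3K_LC,activating
PI3K_LC,AKT_LC,activating
GF_LC,MAPK_LC,activating
Id2_LC,Residency_LC,activating
TNFR_LC,Residency_LC,inhibiting
KC_signal,Residency_LC,inhibiting
AKT_LC,Survival_LC,activating
MAPK_LC,Survival_LC,activating
MAPK_LC,Proliferation_LC,activating
TNFR_LC,Proliferation_LC,activating
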