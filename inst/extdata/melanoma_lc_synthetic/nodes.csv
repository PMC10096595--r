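name,min,max,kind
GF,0,2,secreted
RTK,0,2,receptor
RAS,0,2,protein
BRAF_V600E,0,2,gene
BRAF,0,2,protein
MEK,0,2,protein
ERK,0,2,protein
Ets1,0,2,protein
Sp1,0,2,protein
MITF,0,3,gene
JNK,0,2,protein
Wnt5a,0,2,secreted
cJUN,0,2,protein
TNF,0,2,secreted
TNFR_M,0,2,receptor
IKK,0,2,protein
NFkB,0,2,protein
PTEN,0,2,gene
PI3K,0,2,protein
AKT,0,2,protein
MDM2,0,2,protein
p53,0,2,protein
p21,0,2,protein
CDKN2A,0,2,gene
CyclinD,0,2,protein
CDK4,0,2,complex
E2F,0,2,protein
Proliferation,0,2,process
Apoptosis,0,2,process
TGFB,0,2,secreted
TBR_LC,0,2,receptor
SMAD3_LC,0,2,protein
Id2_LC,0,2,protein
TNFR_LC,0,2,receptor
IL1B,0,2,secreted
IL1R_KC,0,2,receptor
KC_signal,0,2,secreted
GF_LC,0,2,secreted
PI3K_LC,0,2,protein
AKT_LC,0,2,protein
MAPK_LC,0,2,protein
Residency_LC,0,4,process
Survival_LC,0,2,process
Proliferation_LC,0,2,process
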