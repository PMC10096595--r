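drug,class,node,override
dabrafenib,MAPK,BRAF,var(RAS)
vemurafenib,MAPK,BRAF,var(RAS)
trametinib,MAPK,MEK,0
trametinib,MAPK,MAPK_LC,0
ulixertinib,MAPK,ERK,0
ulixertinib,MAPK,MAPK_LC,0
tgfb1_mab,TGFB,TGFB,0
SIS3,TGFB,SMAD3_LC,0
GW788388,TGFB,TBR_LC,0
AGX51,Id2,Id2_LC,0
BMS345541,NFkB,IKK,0
copanlisib,PI3K,PI3K,0
copanlisib,PI3K,PI3K_LC,0
capivasertib,AKT,AKT,0
capivasertib,AKT,AKT_LC,0
idasanutlin,MDM2,MDM2,0
abemaciclib,CDK4,CDK4,0
HLM006474,E2F,E2F,0
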