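id,background,perturbations,readout,expectation_kind,expectation_value
e01,healthy,,TNF,level,0
e02,braf_cdkn2a_pten_mitf_low,,TNF,level,2
e02,braf_cdkn2a_pten_mitf_low,,Residency_LC,level,1
e03,braf_cdkn2a_pten_mitf_high,,Residency_LC,range,1..3
e04,healthy,,Residency_LC,level,4
e05,braf_cdkn2a_pten_mitf_high,drug:dabrafenib,Residency_LC,direction,increase
e06,braf_cdkn2a_pten_mitf_high,drug:tgfb1_mab,Residency_LC,direction,decrease
e07,healthy,drug:GW788388,Residency_LC,direction,decrease
e08,braf_cdkn2a_pten_mitf_low,drug:SIS3,Residency_LC,direction,decrease
e09,braf_cdkn2a_pten_mitf_high,KO:Sp1,Residency_LC,direction,increase
e10,braf_cdkn2a_pten_mitf_low,KO:cJUN,TNF,direction,decrease
e11,braf_cdkn2a_pten_mitf_high,drug:trametinib,Proliferation,direction,decrease
e12,braf_cdkn2a_pten_mitf_high,drug:idasanutlin,Apoptosis,direction,increase
e13,braf_cdkn2a_pten_mitf_high,drug:idasanutlin;drug:abemaciclib,Proliferation,level,0
e13,braf_cdkn2a_pten_mitf_high,drug:idasanutlin;drug:abemaciclib,Apoptosis,level,2
e14,healthy,,Proliferation,level,0
e15,braf_cdkn2a_pten_mitf_high,,Proliferation,level,2
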