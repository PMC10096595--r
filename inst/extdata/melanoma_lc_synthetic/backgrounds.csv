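background,node,level
healthy,GF,1
healthy,BRAF_V600E,0
healthy,MITF,3
healthy,Wnt5a,0
healthy,PTEN,2
healthy,CDKN2A,2
healthy,TGFB,2
healthy,IL1B,0
healthy,GF_LC,2
braf_cdkn2a_pten_mitf_high,GF,1
braf_cdkn2a_pten_mitf_high,BRAF_V600E,2
braf_cdkn2a_pten_mitf_high,MITF,3
braf_cdkn2a_pten_mitf_high,Wnt5a,0
braf_cdkn2a_pten_mitf_high,PTEN,0
braf_cdkn2a_pten_mitf_high,CDKN2A,0
braf_cdkn2a_pten_mitf_high,TGFB,2
braf_cdkn2a_pten_mitf_high,IL1B,1
braf_cdkn2a_pten_mitf_high,GF_LC,2
braf_cdkn2a_pten_mitf_low,GF,1
braf_cdkn2a_pten_mitf_low,BRAF_V600E,2
braf_cdkn2a_pten_mitf_low,MITF,0
braf_cdkn2a_pten_mitf_low,Wnt5a,0
braf_cdkn2a_pten_mitf_low,PTEN,0
braf_cdkn2a_pten_mitf_low,CDKN2A,0
braf_cdkn2a_pten_mitf_low,TGFB,2
braf_cdkn2a_pten_mitf_low,IL1B,1
braf_cdkn2a_pten_mitf_low,GF_LC,2
braf_cdkn2a_mitf_high,GF,1
braf_cdkn2a_mitf_high,BRAF_V600E,2
braf_cdkn2a_mitf_high,MITF,3
braf_cdkn2a_mitf_high,Wnt5a,0
braf_cdkn2a_mitf_high,PTEN,2
braf_cdkn2a_mitf_high,CDKN2A,0
braf_cdkn2a_mitf_high,TGFB,2
braf_cdkn2a_mitf_high,IL1B,1
braf_cdkn2a_mitf_high,GF_LC,2
braf_cdkn2a_mitf_low,GF,1
braf_cdkn2a_mitf_low,BRAF_V600E,2
braf_cdkn2a_mitf_low,MITF,0
braf_cdkn2a_mitf_low,Wnt5a,0
braf_cdkn2a_mitf_low,PTEN,2
braf_cdkn2a_mitf_low,CDKN2A,0
braf_cdkn2a_mitf_low,TGFB,2
braf_cdkn2a_mitf_low,IL1B,1
braf_cdkn2a_mitf_low,GF_LC,2
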