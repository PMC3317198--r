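date,Q_m3_s,pH,T_C,TSS_mg_L,TDS_mg_L,Ca_mg_L,Mg_mg_L,SO4_mg_L,Alk_mgCaCO3_L,Cl_mg_L,Na_mg_L,K_mg_L,DOC_mg_L,TCu_mg_L,PCu_ug_kg,DCu_mg_L
2009-05-15,75.20,7.67,21.43,1637,517,73.33,30.5,207.3,110,101,65.2,5.1,4.4,0.07,0.07,0.001
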