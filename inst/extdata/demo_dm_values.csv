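variable,dm
Q_m3_s,-3.8
pH,1.88
T_C,-4.36
TSS_mg_L,-2.49
TDS_mg_L,4.07
Ca_mg_L,3.09
Mg_mg_L,4.38
SO4_mg_L,4.53
Alk_mgCaCO3_L,1.41
Cl_mg_L,4.04
Na_mg_L,5.79
K_mg_L,1.07
TCu_mg_L,-2.70
PCu_ug_kg,1.73
DCu_mg_L,0.14
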