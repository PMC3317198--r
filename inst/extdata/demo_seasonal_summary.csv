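variable,season,n,mean,median,max,min,std
Q_m3_s,dry,14,57.18,53.22,161.2,6.45,41.40
Q_m3_s,wet,13,248.4,219.07,712.77,6.65,195.22
pH,dry,14,7.87,7.91,8.1,7.31,0.20
pH,wet,13,7.70,7.65,8.33,7.27,0.27
T_C,dry,11,17.54,16.9,25.8,11.8,4.36
T_C,wet,8,25.35,27.15,28.2,17.7,3.68
TSS_mg_L,dry,13,1582.95,1147,8181,92,2178.71
TSS_mg_L,wet,10,14760.2,8990.5,53960,240,17298.53
TDS_mg_L,dry,11,845.7,847,1114,517,211.85
TDS_mg_L,wet,13,469.46,436,1168,170,255.60
Ca_mg_L,dry,14,80.6,79,150.2,44,28.64
Ca_mg_L,wet,13,51.67,44,91,19,23
Mg_mg_L,dry,14,35.22,37.75,52,9.4,11.05
Mg_mg_L,wet,10,17.35,14.5,36,3.4,10.01
SO4_mg_L,dry,12,292.09,278,399.7,190,71.02
SO4_mg_L,wet,11,149.09,135,376,59,87.87
Alk_mgCaCO3_L,dry,12,126.43,121.5,210,91,30.39
Alk_mgCaCO3_L,wet,11,108.71,100,182,57.6,33.07
Cl_mg_L,dry,12,164.91,187.5,243,45,61.53
Cl_mg_L,wet,11,56.85,32,268,20,71.45
Na_mg_L,dry,14,125.97,120.5,207,70,43.06
Na_mg_L,wet,13,48.88,36,131,18,31.33
K_mg_L,dry,14,6.6,6.55,12,3.2,2.29
K_mg_L,wet,13,5.69,5,9.9,3.2,2.38
DOC_mg_L,dry,6,5.27,5.06,10.8,2.2,3.09
TCu_mg_L,dry,13,0.05,0.03,0.18,0.01,0.04
TCu_mg_L,wet,12,0.16,0.11,0.458,0.026,0.15
PCu_ug_kg,dry,12,61.30,34.37,232.75,11.43,72.5
PCu_ug_kg,wet,9,26.58,24.93,53.78,2.724,18.75
DCu_mg_L,dry,14,0.0027,0.002,0.0067,0.001,0.001
DCu_mg_L,wet,13,0.0025,0.0012,0.01,0.0009,0.002
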