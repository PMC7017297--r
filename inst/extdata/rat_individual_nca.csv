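sex,subject,dose_mg_per_kg,lambda_z,t_half,c0,auc_0_inf,auc_per_dose,auc_extrapolated_pct,vz,cl
F,1,12.5,0.174,3.99,43094,23980,1918,0.869,3000,8.7
F,2,12.5,0.187,3.70,47033,24961,1997,0.603,2672,8.3
F,3,12.5,0.187,3.70,64272,31455,2516,0.561,2120,6.6
M,4,12.5,0.178,3.90,49251,24364,1949,0.724,2890,8.6
M,5,12.5,0.184,3.76,86432,34091,2727,0.490,1990,6.1
M,6,12.5,0.175,3.95,44593,23120,1850,0.792,3083,9.0
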