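name,value,units,printed_decimals,group
direct_b,-0.362198,1,6,scaling
direct_log10_a,0.6789,log10(mL/min/kg),4,scaling
direct_cl_per_kg,1.02,mL/min/kg,2,scaling
direct_cl_abs,71.7,mL/min,1,scaling
tang_cl_per_kg,1.1,mL/min/kg,1,scaling
tang_cl_abs,76,mL/min,0,scaling
one_rat_cl_per_kg,1.9,mL/min/kg,1,scaling
one_rat_cl_abs,135,mL/min,0,scaling
one_monkey_cl_per_kg,1.4,mL/min/kg,1,scaling
one_monkey_cl_abs,100,mL/min,0,scaling
gm_cl_total,1.3,mL/min/kg,1,scaling
gm_auc_per_dose_total,12627,h.ng/mL per mg/kg,0,exposure
auc_hed_direct_total,12686,h.ng/mL,0,exposure
auc_hed_tang_total,12046,h.ng/mL,0,exposure
auc_hed_one_rat_total,6741,h.ng/mL,0,exposure
auc_hed_one_monkey_total,9135,h.ng/mL,0,exposure
gm_auc_hed_total,9849,h.ng/mL,0,exposure
gm_auc_noael_total,63135,h.ng/mL,0,exposure
unbound_direct_cl_per_kg,1.0,mL/min/kg,1,scaling
unbound_tang_cl_per_kg,1.15,mL/min/kg,2,scaling
unbound_one_rat_cl_per_kg,2.2,mL/min/kg,1,scaling
unbound_one_monkey_cl_per_kg,1.5,mL/min/kg,1,scaling
gm_cl_unbound,1.4,mL/min/kg,1,scaling
auc_hed_direct_unbound,12781,h.ng/mL,0,exposure
auc_hed_tang_unbound,11280,h.ng/mL,0,exposure
auc_hed_one_rat_unbound,6044,h.ng/mL,0,exposure
auc_hed_one_monkey_unbound,8662,h.ng/mL,0,exposure
gm_auc_hed_unbound,9321,h.ng/mL,0,exposure
range_hed_total_min,6741,h.ng/mL,0,exposure
range_hed_total_max,12686,h.ng/mL,0,exposure
range_hed_unbound_min,6044,h.ng/mL,0,exposure
range_hed_unbound_max,12781,h.ng/mL,0,exposure
noael_rat,5.0,mg/kg/day,1,dose
hed,0.78,mg/kg/day,2,dose
pad_mouse,25,mg/kg,0,dose
pad_human,1.82,mg/kg,2,dose
fu_human,0.0145,fraction,4,binding
fu_monkey,0.0138,fraction,4,binding
fu_rat,0.0130,fraction,4,binding
mean_ppb_human,98.55,percent,2,binding
mean_ppb_monkey,98.63,percent,2,binding
mean_ppb_rat,98.70,percent,2,binding
nsb_1uM,50,percent,0,binding
nsb_10uM,35,percent,0,binding
control_bound_human,89.4,percent,1,binding
noael_auc_rat_female,10398,h.ng/mL,0,exposure
noael_auc_rat_male,12157,h.ng/mL,0,exposure
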