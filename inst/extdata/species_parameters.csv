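species,weight_kg,dose_mg_per_kg,auc_h_ng_ml,cl_printed_ml_min_kg,fu,include_in_scaling,cl_convention
mouse,0.025,25,3226,129,NA,0,dose_over_auc
rat,0.25,12.5,27192,7.9,0.0130,1,per_subject_mean
monkey,3.75,8.75,49300,3.0,0.0138,1,dose_over_auc
human,70,NA,NA,NA,0.0145,0,target
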