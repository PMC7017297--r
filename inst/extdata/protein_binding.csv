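species,test_conc_uM,ppb_mean,ppb_sd,n
human,1,98.6,0.32,3
human,10,98.5,0.09,3
monkey,1,98.2,0.39,3
monkey,10,99.05,0.39,3
rat,1,98.5,0.17,3
rat,10,98.9,0.17,3
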