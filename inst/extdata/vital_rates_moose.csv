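sex,age_from,age_to,winter_survival,birth_rate,summer_survival,dispersal_mean_km,dispersal_sd_km,n_start
F,0,0,0.70,0,0.70,NA,NA,72
F,1,1,0.93,0.07,0.95,2.3,0.4,47
F,2,2,0.93,0.77,0.95,NA,NA,42
F,3,9,0.93,0.90,0.95,NA,NA,180
F,10,10,0.89,0.90,0.92,NA,NA,15
F,11,11,0.84,0.90,0.88,NA,NA,12
F,12,12,0.76,0.90,0.82,NA,NA,9
F,13,NA,0.67,0.90,0.74,NA,NA,11
M,0,0,0.70,0,0.70,NA,NA,72
M,1,1,0.88,0,0.90,9.3,3.1,45
M,2,9,0.88,0,0.90,NA,NA,142
M,10,10,0.82,0,0.85,NA,NA,5
M,11,11,0.74,0,0.78,NA,NA,4
M,12,12,0.64,0,0.69,NA,NA,2
M,13,NA,0.53,0,0.58,NA,NA,1
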