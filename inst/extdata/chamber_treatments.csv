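experiment,treatment,tday_c,tnight_c,par_umol_m2_s,photoperiod_h,co2_ppm,swap_par_umol_m2_s,swap_trigger_hs,par_mol_m2_d,tt_cd,ptq,lar_i_e3,lar_i_sd_e3
1,HT.SD.320,28,24,320,8,400,NA,NA,9.4,24.5,0.38,6.61,0.37
1,HT.LD.170,28,24,170,16,400,NA,NA,9.6,26.2,0.37,6.63,0.47
1,HT.LD.280,28,24,280,16,400,NA,NA,16.5,26.2,0.63,7.94,0.22
1,LT.LD.280,18,14,280,16,400,NA,NA,15.9,10.3,1.54,10.84,0.52
1,HT.MD.450,28,24,450,14,400,NA,NA,22.5,26.4,0.85,7.75,0.83
1,LT.MD.320,18,14,320,14,400,NA,NA,15.7,10.5,1.50,9.17,0.71
1,280-170,28,24,280,16,400,170,3.5,16.5,26.2,0.63,7.80,0.52
1,170-280,28,24,170,16,400,280,3.5,9.6,26.2,0.37,6.49,0.43
2,HT.aCO2,28,24,600,14,400,NA,NA,32.3,27.2,1.19,10.80,0.56
2,HT.eCO2,28,24,600,14,800,NA,NA,27.8,27.2,1.02,11.90,0.64
2,LT.aCO2,18,14,600,14,400,NA,NA,31.5,10.6,2.97,11.20,1.19
2,LT.eCO2,18,14,600,14,800,NA,NA,30.0,10.6,2.83,15.80,0.83
3,HT.SD,28,24,190,8,400,NA,NA,4.9,25.5,0.20,5.00,0.39
3,HT.LD,28,24,190,16,400,NA,NA,11.1,26.7,0.42,6.62,0.54
3,LT.SD,18,14,190,8,400,NA,NA,5.7,8.9,0.64,6.58,0.42
3,LT.LD,18,14,190,16,400,NA,NA,10.6,10.1,1.05,8.40,0.59
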