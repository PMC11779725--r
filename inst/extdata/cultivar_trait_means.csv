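cultivar,SW,SW_sd,SL,SL_sd,SA,SA_sd,SP,SP_sd,SR,SR_sd,SE,SE_sd,SCA,SCA_sd,PSCA,PSCA_sd,GCPA,GCPA_sd,PGCPA,PGCPA_sd,SD,SD_sd
2416,55.45,2.24,90.68,7.15,3809.86,372.17,281.48,22.74,0.61,0.05,0.77,0.05,1891.25,267.53,0.49,0.06,1919.61,274.43,0.50,0.06,87.21,10.97
MC01,56.66,4.16,94.09,8.55,4053.70,538.99,281.63,23.36,0.65,0.04,0.78,0.04,2102.48,373.74,0.52,0.06,1951.22,318.97,0.48,0.06,78.64,9.41
728,55.86,3.25,97.20,8.39,4140.05,464.19,288.45,22.74,0.63,0.04,0.80,0.04,2122.02,366.05,0.51,0.06,2018.03,287.81,0.49,0.06,74.95,11.82
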