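crop,genotype,epsilon_e,epsilon_e_se,epsilon_t,epsilon_t_se,epsilon_c,epsilon_c_se
maize,B106,0.5,0.001,0.057,0.003,0.029,0.001
maize,B73,0.497,0.001,0.065,0.003,0.033,0.002
maize,Badischer Gelber,0.479,0.001,0.065,0.005,0.033,0.003
maize,E,0.53,0.001,0.056,0.005,0.03,0.003
maize,EC334,0.531,0.001,0.053,0.003,0.028,0.001
maize,N22,0.527,0.001,0.093,0.005,0.049,0.003
maize,P135,0.549,0.001,0.063,0.003,0.034,0.002
maize,P148,0.528,0.001,0.075,0.003,0.04,0.001
maize,PHT77,0.556,0.001,0.07,0.003,0.039,0.001
maize,PO74,0.539,0.001,0.066,0.003,0.035,0.001
maize,SO52,0.557,0.001,0.085,0.003,0.047,0.001
maize,W117,0.495,0.001,0.057,0.003,0.029,0.001
soybean,22216,0.499,0.022,0.021,0.004,0.01,0.002
soybean,Amarok,0.506,0.023,0.022,0.004,0.011,0.002
soybean,Ascasubi,0.622,0.029,0.049,0.006,0.03,0.003
soybean,Bahia,0.544,0.018,0.051,0.003,0.028,0.002
soybean,Eiko,0.533,0.019,0.05,0.004,0.026,0.002
soybean,Gallec,0.515,0.023,0.024,0.004,0.012,0.002
soybean,MinnGold,0.503,0.015,0.041,0.003,0.021,0.002
soybean,S1,0.508,0.023,0.012,0.004,0.006,0.002
soybean,Tourmaline,0.51,0.023,0.036,0.004,0.018,0.002
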