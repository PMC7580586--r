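element,mean_ppb,sd_ppb,soil_fur_r2,soil_fur_p,significant
Al,18.814,15.537,0.010,0.21,FALSE
Ni,2.254,2.663,0.010,0.45,FALSE
Cu,6.237,3.053,0.015,0.35,FALSE
Rb,0.652,0.352,0.073,0.04,TRUE
Y,0.378,0.199,0.062,0.06,FALSE
Mo,1.585,0.805,0.154,0.01,TRUE
Sn,4.225,5.169,0.071,0.04,TRUE
Ba,5.415,3.010,0.001,0.77,FALSE
Cs,0.914,2.609,0.002,0.34,FALSE
Ce,0.325,0.159,0.001,0.62,FALSE
Hg,4.777,4.431,0.004,0.63,FALSE
Mg,51.891,24.056,0.120,0.46,FALSE
Mn,1.297,0.677,0.021,0.27,FALSE
Fe,65.486,80.390,0.001,0.78,FALSE
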