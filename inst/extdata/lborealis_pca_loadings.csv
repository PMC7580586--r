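element,pc1_loading,pc1_weight,pc2_loading,pc2_weight,pc3_loading,pc3_weight
Al,0.07,1.39,0.15,2.77,0.39,7.41
Ni,0.23,0.51,-0.06,-0.12,-0.17,-0.38
Cu,0.21,1.28,0.06,0.35,0.21,1.32
Rb,0.27,0.18,-0.05,-0.03,-0.18,-0.12
Y,0.27,0.10,-0.06,-0.02,-0.19,-0.07
Mo,0.27,0.43,-0.04,-0.06,-0.19,-0.30
Sn,0.15,0.61,-0.03,-0.13,0.09,0.38
Ba,0.28,1.51,0.02,0.12,0.04,0.23
Cs,-0.03,-0.03,0.02,0.02,0.08,0.08
Ce,0.27,0.09,-0.06,-0.02,-0.16,-0.05
Hg,0.16,0.78,0.06,0.26,0.30,1.45
Mg,0.18,9.55,-0.01,-0.52,0.03,1.71
Mn,0.06,0.08,0.53,0.69,-0.18,-0.23
Fe,-0.02,-1.18,0.56,36.61,-0.15,-10.08
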