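state,frequency_khz,tumor_type,n,mean_s_per_m,sd_s_per_m
in_vivo,3,CCA,2,0.35,NA
in_vivo,3,HCC,5,0.42,0.13
in_vivo,3,MET,6,0.41,0.08
in_vivo,30,CCA,2,0.38,NA
in_vivo,30,HCC,5,0.47,0.15
in_vivo,30,MET,5,0.44,0.08
in_vivo,300,CCA,2,0.53,NA
in_vivo,300,HCC,5,0.60,0.17
in_vivo,300,MET,5,0.52,0.04
in_vivo,607,CCA,1,0.70,NA
in_vivo,607,HCC,5,0.80,0.30
in_vivo,607,MET,4,0.58,0.10
in_vivo,1000,CCA,1,0.89,NA
in_vivo,1000,HCC,5,0.88,0.31
in_vivo,1000,MET,5,0.67,0.14
ex_vivo,3,CCA,1,0.28,NA
ex_vivo,3,HCC,6,0.23,0.09
ex_vivo,3,MET,6,0.33,0.07
ex_vivo,30,CCA,2,0.30,NA
ex_vivo,30,HCC,6,0.25,0.10
ex_vivo,30,MET,6,0.36,0.06
ex_vivo,300,CCA,2,0.43,NA
ex_vivo,300,HCC,6,0.34,0.11
ex_vivo,300,MET,5,0.42,0.03
ex_vivo,607,CCA,2,0.58,NA
ex_vivo,607,HCC,6,0.41,0.14
ex_vivo,607,MET,4,0.51,0.01
ex_vivo,1000,CCA,2,0.73,NA
ex_vivo,1000,HCC,6,0.48,0.17
ex_vivo,1000,MET,6,0.60,0.02
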