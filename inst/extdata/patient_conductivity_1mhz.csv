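patient,disease,tumor_size_mm,cirrhotic,sigma_in_vivo_normal,sigma_ex_vivo_normal,sigma_in_vivo_tumor,sigma_ex_vivo_tumor,typo_normalized
1,CCA,88 x 76 x 70,FALSE,0.71,0.37,0.9,0.73,FALSE
2,HCC,67 x 50 x 45,FALSE,0.43,0.54,NA,0.78,FALSE
3,MET,8 x 6 x 6,FALSE,0.43,NA,0.5,NA,FALSE
4,HCC,27 x 20 x 16,TRUE,0.43,0.50,0.8,0.45,FALSE
5,HCC,43 x 33 x 21,FALSE,0.43,0.27,NA,NA,FALSE
6,HCC,19 x 19,FALSE,0.43,0.74,NA,NA,FALSE
7,MET,35 x 25 x 31,FALSE,0.43,0.31,1.1,0.63,FALSE
8,MET,40 x 24 x 37,FALSE,0.43,0.67,0.8,0.62,FALSE
9,HCC,23 x 17 x 15,TRUE,0.43,0.41,0.7,NA,FALSE
10,MET,24 x 20 x 26,FALSE,0.43,0.29,0.6,0.62,TRUE
11,HCC,24 x 22 x 19,FALSE,NA,NA,NA,NA,FALSE
12,HCC,33 x 25 x 22,TRUE,0.40,0.32,0.5,0.28,FALSE
13,MET,22 x 16 x 13,FALSE,0.41,0.35,0.8,0.61,FALSE
14,MET,26 (Diameter),FALSE,0.56,0.38,0.7,0.44,FALSE
15,HCC,85 x 80 x 65,FALSE,0.60,0.47,1.1,0.54,FALSE
16,HCC,10 x 7 x 6,FALSE,0.52,0.42,0.9,0.34,FALSE
17,HCC,57 x 48 x 48,FALSE,0.72,0.44,1.4,0.52,FALSE
18,MET,34 x 32 x 24,FALSE,0.45,0.35,0.7,0.56,FALSE
19,HCC,10 x 1 x 1,FALSE,0.47,0.04,0.9,0.44,FALSE
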