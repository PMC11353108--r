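tissue_class,state,n,frequency_khz,mean_s_per_m,sd_s_per_m,printed_mean,typo_normalized
normal,in_vivo,15,3,0.13,0.06,0.13,FALSE
normal,in_vivo,15,30,0.17,0.06,0.17,FALSE
normal,in_vivo,15,300,0.30,0.12,0.30,FALSE
normal,in_vivo,15,607,0.39,0.11,0.39,FALSE
normal,in_vivo,15,1000,0.49,0.10,0.49,FALSE
normal,ex_vivo,16,3,0.12,0.07,012,TRUE
normal,ex_vivo,16,30,0.16,0.09,0.16,FALSE
normal,ex_vivo,16,300,0.26,0.10,0.26,FALSE
normal,ex_vivo,16,607,0.34,0.10,0.34,FALSE
normal,ex_vivo,16,1000,0.38,0.08,0.38,FALSE
tumor,in_vivo,16,3,0.41,0.10,0.41,FALSE
tumor,in_vivo,16,30,0.45,0.10,0.45,FALSE
tumor,in_vivo,16,300,0.57,0.12,0.57,FALSE
tumor,in_vivo,16,607,0.69,0.22,0.69,FALSE
tumor,in_vivo,16,1000,0.78,0.24,0.78,FALSE
tumor,ex_vivo,3,3,0.27,0.09,0.27,FALSE
tumor,ex_vivo,3,30,0.30,0.09,0.30,FALSE
tumor,ex_vivo,3,300,0.38,0.08,0.38,FALSE
tumor,ex_vivo,3,607,0.45,0.11,0.45,FALSE
tumor,ex_vivo,3,1000,0.54,0.14,0.54,FALSE
cirrhotic,in_vivo,3,3,0.09,0.01,0.09,FALSE
cirrhotic,in_vivo,3,30,0.11,0.02,0.11,FALSE
cirrhotic,in_vivo,3,300,0.22,0.02,0.22,FALSE
cirrhotic,in_vivo,3,607,0.31,0.009,0.31,FALSE
cirrhotic,in_vivo,3,1000,0.41,0.01,041,TRUE
cirrhotic,ex_vivo,3,3,0.16,0.01,0.16,FALSE
cirrhotic,ex_vivo,3,30,0.18,0.02,0.18,FALSE
cirrhotic,ex_vivo,3,300,0.29,0.05,0.29,FALSE
cirrhotic,ex_vivo,3,607,0.35,0.07,0.35,FALSE
cirrhotic,ex_vivo,3,1000,0.40,0.08,0.40,FALSE
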