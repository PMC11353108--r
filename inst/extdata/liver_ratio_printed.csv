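frequency_khz,ratio,value
3,Tin/Nin,3.2
3,Tin/Tex,1.5
3,Tex/Nin,2.1
3,Tin/Cin,4.4
3,Tex/Cin,3.0
3,Nin/Cin,1.4
30,Tin/Nin,2.7
30,Tin/Tex,1.5
30,Tex/Nin,1.8
30,Tin/Cin,3.8
30,Tex/Cin,2.6
30,Nin/Cin,1.4
300,Tin/Nin,1.9
300,Tin/Tex,1.5
300,Tex/Nin,1.2
300,Tin/Cin,2.5
300,Tex/Cin,1.7
300,Nin/Cin,1.3
607,Tin/Nin,1.8
607,Tin/Tex,1.5
607,Tex/Nin,1.1
607,Tin/Cin,2.2
607,Tex/Cin,1.5
607,Nin/Cin,1.3
1000,Tin/Nin,1.6
1000,Tin/Tex,1.4
1000,Tex/Nin,1.1
1000,Tin/Cin,1.9
1000,Tex/Cin,1.3
1000,Nin/Cin,1.2
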