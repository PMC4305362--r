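response,level_a,level_b,mean,sem,letter
Asp,HF,Lean,45.3,2.39,
Asp,HF,Overweight,47.6,2.97,
Asp,LF,Lean,46.2,2.96,
Asp,LF,Overweight,45.3,3.45,
Glu,HF,Lean,88.4,3.23,
Glu,HF,Overweight,88.6,1.16,
Glu,LF,Lean,87.8,2.58,
Glu,LF,Overweight,87.6,3.18,
Asn,HF,Lean,128,5.71,
Asn,HF,Overweight,114,10.4,
Asn,LF,Lean,120,5.62,
Asn,LF,Overweight,133,6.58,
Ser,HF,Lean,359,10.3,a
Ser,HF,Overweight,294,4.39,b
Ser,LF,Lean,353,7.43,a
Ser,LF,Overweight,292,3.76,b
Gln,HF,Lean,562,18.3,b
Gln,HF,Overweight,645,11.1,a
Gln,LF,Lean,559,9.43,b
Gln,LF,Overweight,655,19.6,a
His,HF,Lean,124,3.18,
His,HF,Overweight,115,2.95,
His,LF,Lean,120,4.08,
His,LF,Overweight,130,5.89,
Gly,HF,Lean,392,6.91,a
Gly,HF,Overweight,305,7.3,b
Gly,LF,Lean,384,7.32,a
Gly,LF,Overweight,297,5.68,b
Thr,HF,Lean,379,7.42,
Thr,HF,Overweight,359,11.6,
Thr,LF,Lean,381,8.62,
Thr,LF,Overweight,376,12.6,
Cit,HF,Lean,79.9,2.66,a
Cit,HF,Overweight,53.8,1.63,c
Cit,LF,Lean,69.6,3.37,b
Cit,LF,Overweight,73.9,1.84,ab
Arg,HF,Lean,251,8.09,b
Arg,HF,Overweight,197,6.4,c
Arg,LF,Lean,279,7.46,a
Arg,LF,Overweight,219,4.46,c
beta_Ala,HF,Lean,13.6,0.884,b
beta_Ala,HF,Overweight,31.4,1.52,a
beta_Ala,LF,Lean,13.1,0.611,b
beta_Ala,LF,Overweight,26.8,1.91,a
Taurine,HF,Lean,648,17.2,a
Taurine,HF,Overweight,469,13.1,c
Taurine,LF,Lean,670,11.9,a
Taurine,LF,Overweight,572,12,b
Ala,HF,Lean,471,10.2,b
Ala,HF,Overweight,403,13.6,c
Ala,LF,Lean,492,7.54,b
Ala,LF,Overweight,585,9.22,a
Tyr,HF,Lean,131,4.25,
Tyr,HF,Overweight,135,4.04,
Tyr,LF,Lean,125,5.7,
Tyr,LF,Overweight,139,5.32,
Trp,HF,Lean,110,3.28,
Trp,HF,Overweight,114,4.78,
Trp,LF,Lean,115,2.61,
Trp,LF,Overweight,113,3.4,
Met,HF,Lean,108,5.39,
Met,HF,Overweight,112,3.65,
Met,LF,Lean,107,4.83,
Met,LF,Overweight,110,4.8,
Val,HF,Lean,253,9.61,c
Val,HF,Overweight,331,6.74,a
Val,LF,Lean,249,10.1,c
Val,LF,Overweight,289,9.63,b
Phe,HF,Lean,111,3.7,
Phe,HF,Overweight,108,3.84,
Phe,LF,Lean,106,3.81,
Phe,LF,Overweight,113,3.44,
Ile,HF,Lean,152,4.19,b
Ile,HF,Overweight,206,4.01,a
Ile,LF,Lean,144,4.77,b
Ile,LF,Overweight,195,3.68,a
Leu,HF,Lean,212,4.56,b
Leu,HF,Overweight,308,7.56,a
Leu,LF,Lean,216,6.34,b
Leu,LF,Overweight,302,5.79,a
Orn,HF,Lean,68.8,1.58,b
Orn,HF,Overweight,81.4,1.51,a
Orn,LF,Lean,67.8,2.06,b
Orn,LF,Overweight,83.3,1.25,a
Pro,HF,Lean,277,7.04,b
Pro,HF,Overweight,342,8.59,a
Pro,LF,Lean,286,5.32,b
Pro,LF,Overweight,334,4.52,a
Cys,HF,Lean,165,4.53,b
Cys,HF,Overweight,197,7,a
Cys,LF,Lean,157,3.2,b
Cys,LF,Overweight,194,6.58,a
Lys,HF,Lean,252,8.82,c
Lys,HF,Overweight,291,5.17,a
Lys,LF,Lean,259,8.32,bc
Lys,LF,Overweight,282,5.42,ab
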