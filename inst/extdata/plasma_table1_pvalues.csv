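response,p_diet,p_weight,p_interaction
Asp,0.824,0.824,0.604
Glu,0.757,0.984,0.951
Asn,0.477,0.922,0.068
Ser,0.576,<0.001,0.807
Gln,0.801,<0.001,0.676
His,0.236,0.906,0.028
Gly,0.254,<0.001,0.955
Thr,0.365,0.223,0.481
Cit,0.057,<0.001,<0.001
Arg,0.001,<0.001,0.642
beta_Ala,0.064,<0.001,0.123
Taurine,<0.001,<0.001,0.006
Ala,<0.001,0.252,<0.001
Tyr,0.865,0.069,0.268
Trp,0.658,0.703,0.42
Met,0.77,0.521,0.991
Val,0.017,<0.001,0.048
Phe,0.988,0.645,0.211
Ile,0.035,<0.001,0.674
Leu,0.83,<0.001,0.465
Orn,0.786,<0.001,0.381
Pro,0.96,<0.001,0.196
Cys,0.279,<0.001,0.648
Lys,0.957,<0.001,0.273
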