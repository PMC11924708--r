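id,congruent,hypothesis,theta_h,theta_c,theta_t,delta,margin_m
1,TRUE,H0,0.179,0.179,0.219,0.02,0.04
2,TRUE,H1,0.179,0.179,0.179,0.02,0.04
3,FALSE,H0,0.179,0.159,0.199,0.02,0.04
4,FALSE,H1,0.179,0.159,0.159,0.02,0.04
5,FALSE,H0,0.179,0.149,0.189,0.02,0.04
6,FALSE,H1,0.179,0.149,0.149,0.02,0.04
7,FALSE,H0,0.179,0.139,0.179,0.02,0.04
8,FALSE,H1,0.179,0.139,0.139,0.02,0.04
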