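participant_id,visit,time_min,glucose_mmol_l,insulin_mu_l
E1,baseline,0,5,10
E1,baseline,30,5,10
E1,baseline,60,5,10
E1,baseline,90,5,10
E1,baseline,120,5,10
E2,baseline,0,11.98,23.9
E2,baseline,30,14.5,31
E2,baseline,60,17.2,39
E2,baseline,90,19.3,45
E2,baseline,120,21.38,51
E3,month3,0,8.2,15
E3,month3,30,10.4,22
E3,month3,60,12.1,28
E3,month3,120,11.5,30
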