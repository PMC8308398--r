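participant_id,visit,hba1c_mmol_mol,fpg_mmol_l
P01,baseline,47,7.5
P02,baseline,68,11.5
P03,baseline,67,12.0
P04,baseline,66,11.8
P05,baseline,64,11.2
P06,baseline,69,12.4
P07,baseline,75,13.0
P08,baseline,71,12.6
P09,baseline,70,12.2
P10,baseline,65,11.6
P11,baseline,72,12.8
P12,baseline,68,12.1
P13,baseline,62,10.9
P14,baseline,60,10.5
P15,baseline,66,11.0
P01,month3,32,5.5
P02,month3,45,6.2
P03,month3,50,7.5
P04,month3,52,7.8
P05,month3,44,6.8
P06,month3,51,7.9
P07,month3,60,9.8
P08,month3,58,9.2
P09,month3,57,9.0
P10,month3,55,8.6
P11,month3,61,9.9
P12,month3,56,8.8
P13,month3,54,8.4
P14,month3,55,8.5
P15,month3,58,9.8
P01,month6,36,5.8
P02,month6,46,6.5
P03,month6,49,7.6
P04,month6,50,7.7
P05,month6,47,6.9
P06,month6,60,9.5
P07,month6,64,10.5
P08,month6,62,10.1
P09,month6,60,9.6
P10,month6,58,9.2
P11,month6,66,10.8
P12,month6,59,9.4
P13,month6,57,9.0
P14,month6,58,9.1
P15,month6,58,9.8
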