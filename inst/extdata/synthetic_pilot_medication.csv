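participant_id,visit,drug_class,daily_dose,dose_unit
P01,baseline,metformin,2000,mg
P02,baseline,metformin,2000,mg
P03,baseline,metformin,2000,mg
P03,baseline,SU_derivative,80,mg
P04,baseline,metformin,2000,mg
P04,baseline,SU_derivative,80,mg
P05,baseline,metformin,2000,mg
P06,baseline,metformin,2000,mg
P06,baseline,insulin,40,IU
P07,baseline,metformin,2000,mg
P07,baseline,SU_derivative,80,mg
P07,baseline,insulin,52,IU
P08,baseline,metformin,1500,mg
P08,baseline,GLP1_agonist,1.5,mg
P08,baseline,insulin,36,IU
P09,baseline,metformin,2000,mg
P09,baseline,insulin,44,IU
P10,baseline,metformin,2000,mg
P10,baseline,SU_derivative,80,mg
P11,baseline,metformin,2500,mg
P11,baseline,SU_derivative,120,mg
P12,baseline,metformin,2000,mg
P12,baseline,SU_derivative,80,mg
P13,baseline,metformin,1000,mg
P14,baseline,metformin,2000,mg
P15,baseline,none,,
P01,month3,none,,
P02,month3,none,,
P03,month3,metformin,2000,mg
P04,month3,metformin,1000,mg
P05,month3,metformin,2000,mg
P06,month3,metformin,1000,mg
P07,month3,metformin,2000,mg
P08,month3,metformin,1500,mg
P08,month3,GLP1_agonist,1.5,mg
P09,month3,metformin,2000,mg
P10,month3,metformin,2000,mg
P11,month3,metformin,2500,mg
P12,month3,metformin,2000,mg
P13,month3,metformin,1000,mg
P14,month3,metformin,2000,mg
P15,month3,none,,
P01,month6,none,,
P02,month6,none,,
P03,month6,metformin,2000,mg
P04,month6,metformin,1000,mg
P05,month6,metformin,2000,mg
P06,month6,metformin,2000,mg
P07,month6,metformin,2000,mg
P08,month6,metformin,1500,mg
P08,month6,GLP1_agonist,1.5,mg
P09,month6,metformin,2000,mg
P10,month6,metformin,2000,mg
P11,month6,metformin,2500,mg
P12,month6,metformin,2000,mg
P13,month6,metformin,1000,mg
P14,month6,metformin,2000,mg
P15,month6,none,,
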