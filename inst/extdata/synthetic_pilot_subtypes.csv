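participant_id,visit,label
P01,baseline,IB-HIR
P02,baseline,IB-HIR
P03,baseline,IB-HIR
P04,baseline,IB-HIR
P05,baseline,IB-HIR
P06,baseline,IB-HIR
P07,baseline,IB-HIR
P08,baseline,IB-HIR
P09,baseline,IB-HIR
P10,baseline,IB-HIR
P11,baseline,IB-HIR
P12,baseline,IB-HIR
P13,baseline,IB
P01,month3,IB-HIR
P02,month3,IB-HIR
P03,month3,IB-HIR
P04,month3,IB-HIR
P05,month3,IB-HIR
P06,month3,IB-HIR
P07,month3,IB-HIR
P08,month3,IB-CIR
P09,month3,IB-CIR
P10,month3,IB-CIR
P11,month3,IB-CIR
P12,month3,IB-CIR
P13,month3,IB
P14,month3,IB-CIR
P15,month3,IB-CIR
P01,month6,IB-HIR
P02,month6,IB-HIR
P03,month6,IB-HIR
P04,month6,IB-HIR
P05,month6,IB-HIR
P06,month6,IB-HIR
P07,month6,IB-HIR
P08,month6,IB-HIR
P09,month6,IB-CIR
P10,month6,IB-CIR
P11,month6,IB-CIR
P12,month6,IB-CIR
P13,month6,IB-HIR
P14,month6,IB-HIR
P15,month6,IB-CIR
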