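arm_id,entry,exit
T1,0,14
T2,1,15
T3,2,16
T4,10,24
T5,11,25
T6,12,26
T7,21,35
T8,22,36
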