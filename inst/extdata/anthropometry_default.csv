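level,body_height,disc_below,mass_fraction
T1,16,4,0.188
T2,17,4,0.021
T3,17,4,0.021
T4,18,4,0.021
T5,18,4.5,0.021
T6,19,4.5,0.021
T7,19,4.5,0.021
T8,20,4.5,0.021
T9,20,5,0.021
T10,21,5,0.021
T11,22,6,0.021
T12,23,7,0.021
L1,25,8,0.035
L2,26,9,0.035
L3,27,10,0.035
L4,27,11,0.035
L5,26,11,0.035
S1,32,NA,0
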