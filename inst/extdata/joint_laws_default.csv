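junction,k0,c,theta_ref,kappa,shear,axial,rom_lo,rom_hi
T1-T2,0.6,1.5,4,2,300,1500,2,5.5
T2-T3,0.6,1.5,4,2,300,1500,2,5.5
T3-T4,0.6,1.5,4,2,300,1500,2,5.5
T4-T5,0.6,1.5,4,2,300,1500,2,5.5
T5-T6,0.6,1.5,4,2,300,1500,2,5.5
T6-T7,0.6,1.5,4,2,300,1500,2,5.5
T7-T8,0.6,1.5,4,2,300,1500,2,5.5
T8-T9,0.6,1.5,4,2,300,1500,2,5.5
T9-T10,0.6,1.5,4,2,300,1500,2,5.5
T10-T11,0.6,1.5,4,2,300,1500,2,5.5
T11-T12,0.6,1.5,4,2,300,1500,2,5.5
T12-L1,0.7,1.8,4,1,280,1300,2.5,6
L1-L2,0.8,2.2,4,1,260,1200,3,7
L2-L3,0.8,2.2,4,1,260,1200,3,7
L3-L4,0.8,2.2,4,1,260,1200,3,7
L4-L5,0.8,2.2,4,1,260,1200,3,7
L5-S1,0.8,2.2,4,1,260,1200,3,7
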