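label,ang,rad
Fp1,-18,0.511
Fp2,18,0.511
F7,-54,0.511
F3,-39,0.333
Fz,0,0.256
F4,39,0.333
F8,54,0.511
T7,-90,0.511
C3,-90,0.256
Cz,0,0
C4,90,0.256
T8,90,0.511
P7,-126,0.511
P3,-141,0.333
Pz,180,0.256
P4,141,0.333
P8,126,0.511
O1,-162,0.511
O2,162,0.511
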