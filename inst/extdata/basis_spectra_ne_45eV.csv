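species,mz,intensity,detector,electron_energy
H2O,17,0.164,M,45
H2O,18,1.0,M,45
H2O,20,1.34e-3,M,45
NE20,20,1.0,M,45
AR,20,1.06e-9,M,45
AR,36,3.00e-3,M,45
AR,40,1.0,M,45
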