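species,mz,intensity,detector,electron_energy
CH4,14,0.103,F,70
CH4,15,0.806,F,70
CH4,16,1.0,F,70
N2,14,0.059,F,70
N2,15,0.00012,F,70
N2,28,1.0,F,70
AIR,14,0.059,F,70
AIR,15,0.00014,F,70
AIR,16,0.0158,F,70
AIR,28,1.0,F,70
AIR,32,0.208,F,70
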