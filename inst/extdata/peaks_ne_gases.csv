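gas,mz,detector,y,dy,unit,role
GAS-III,17,M,24.0,0.1,nA,main
GAS-III,20,M,0.748,0.008,nA,main
GAS-III,36,M,4.59,0.02,nA,main
GAS-IV,17,M,96.4,0.4,nA,main
GAS-IV,20,M,1.37,0.02,nA,main
GAS-IV,36,M,4.91,0.02,nA,main
GAS-V,17,M,20.6,0.1,nA,main
GAS-V,20,M,0.197,0.002,nA,main
GAS-V,36,M,2.29,0.01,nA,main
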