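gas,mz,detector,y,dy,unit,role
GAS-I,14,F,127,2,pA,main
GAS-I,15,F,394,6,pA,main
GAS-I,16,F,491,5,pA,main
GAS-I,28,F,1123,8,pA,main
GAS-I,32,F,2.6,0.9,pA,main
GAS-II,14,F,77.6,0.9,pA,main
GAS-II,15,F,0.629,0.008,pA,main
GAS-II,16,F,22.7,0.1,pA,main
GAS-II,28,F,1327,6,pA,main
GAS-II,32,F,271,5,pA,main
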