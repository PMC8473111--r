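"",LC,RC,LL,LR,WB,SS
LC,581,0,16,0,3,0
RC,0,578,0,18,4,0
LL,18,0,571,0,10,1
LR,0,18,0,577,5,0
WB,3,6,11,10,533,37
SS,4,0,16,10,35,535
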