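"",LC,RC,LL,LR,WB,SS
LC,600,0,0,0,0,0
RC,0,600,0,0,0,0
LL,15,0,574,0,7,4
LR,0,11,0,584,4,1
WB,1,2,12,14,545,26
SS,0,0,9,11,39,541
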