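Culture,Representation,sp1,sp2,sp3,sp4,sp5
c1,1,0,25,39,27,9
c2,1,110,10,0,0,0
c3,1,0,26,24,28,10
c4,1,0,11,119,0,0
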