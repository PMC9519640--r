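marshall,niris0,niris1,niris2,niris3,niris4
I,319,14,6,0,0
II,1,208,739,72,7
III,0,3,232,54,4
IV,0,0,2,28,18
V_VI,0,0,318,372,634
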