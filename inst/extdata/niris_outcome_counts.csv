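category,n,dead_icu,dead_hospital,dead_6mo
0,320,9,19,27
1,225,2,6,12
2,1297,63,105,220
3,526,38,72,142
4,663,108,187,309
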