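grade,n_mitochondria
1,505
2,1048
3,2128
4,3460
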