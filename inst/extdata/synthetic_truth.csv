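gene1,gene2,flag
A,B,1
A,N1,0
N1,N2,0
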