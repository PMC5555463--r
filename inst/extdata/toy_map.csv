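name,chromosome,position
RM471,4,0
DGS1,4,2.9
RM1359,4,6.8
RM1353,7,0
DGS2,7,9.2
RM6081,7,13.1
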