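plant,RM471,RM6081,fertile,total
1,A,H,200,200
2,H,A,101,200
3,B,B,198,200
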