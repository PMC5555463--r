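class,observed
AA|AA,9
AA|AB,14
AA|BB,9
AB|AA,10
AB|AB,18
AB|BB,15
BB|AA,0
BB|AB,7
BB|BB,8
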