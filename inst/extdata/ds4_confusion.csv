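class,N,F
N,89878,8
F,188,614
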