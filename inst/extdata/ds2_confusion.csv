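class,N,S
N,89819,67
S,347,2426
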