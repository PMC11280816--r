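class,N,V
N,89802,85
V,254,6743
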