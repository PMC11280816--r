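class,N,S,V,F
N,89768,53,60,5
S,326,2420,26,1
V,178,10,6770,38
F,144,2,55,601
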