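class,Nb,Ab
Nb,89673,213
Ab,786,9785
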