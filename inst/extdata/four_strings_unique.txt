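1000111
1110001
1100011
1010011
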