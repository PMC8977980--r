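gender,n,n_rac
men,64,47
women,21,8
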