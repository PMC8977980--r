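class,n,recurrence
none,29,9
inside_only,9,1
outside,41,26
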