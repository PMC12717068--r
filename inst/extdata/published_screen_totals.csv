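interval,n_screens
annual,2542382
biennial,752049
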