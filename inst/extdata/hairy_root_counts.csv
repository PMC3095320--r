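n_analyzed,n_positive,n_negative
195,140,55
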