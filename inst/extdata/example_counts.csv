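tp,fp,fn,tn
52,7,16,129
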