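height,weight,PBF
175,65,21.2
177,62,19.7
180,68,20.9
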