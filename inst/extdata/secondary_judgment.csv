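,HF,HP,HB
HF,1,0.95,1.05
HP,1.0526,1,1.2
HB,0.9524,0.8333,1
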