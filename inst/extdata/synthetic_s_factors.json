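{"Mo-Mo":1,"Mo-Rh":1.017,"Rh-Rh":1.061,"W-Rh":1.042,"W-Ag":1.042}
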