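,2,3,4,5,6,7
0.3,0.97,1,1.03,1.06,1.09,1.12
0.4,0.98,1.01,1.04,1.07,1.1,1.13
0.5,0.99,1.02,1.05,1.08,1.11,1.14
0.6,1,1.03,1.06,1.09,1.12,1.15
0.7,1.01,1.04,1.07,1.1,1.13,1.16
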