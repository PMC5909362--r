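,2,3,4,5,6,7
0.3,0.93,0.958,0.986,1.014,1.042,1.07
0.4,0.942,0.97,0.998,1.026,1.054,1.082
0.5,0.954,0.982,1.01,1.038,1.066,1.094
0.6,0.966,0.994,1.022,1.05,1.078,1.106
0.7,0.978,1.006,1.034,1.062,1.09,1.118
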