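,2,3,4,5,6,7
0.3,0.4502,0.3836,0.3269,0.2786,0.2374,0.2023
0.4,0.4907,0.4182,0.3563,0.3037,0.2588,0.2205
0.5,0.5313,0.4527,0.3858,0.3287,0.2801,0.2387
0.6,0.5718,0.4872,0.4152,0.3538,0.3015,0.2569
0.7,0.6123,0.5218,0.4446,0.3789,0.3229,0.2751
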