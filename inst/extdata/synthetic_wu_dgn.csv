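,2,3,4,5,6,7
0.3,0.4128,0.3483,0.2938,0.2479,0.2091,0.1764
0.4,0.4582,0.3866,0.3262,0.2752,0.2322,0.1959
0.5,0.5036,0.4249,0.3585,0.3024,0.2552,0.2153
0.6,0.5491,0.4632,0.3908,0.3297,0.2782,0.2347
0.7,0.5945,0.5015,0.4231,0.357,0.3012,0.2541
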