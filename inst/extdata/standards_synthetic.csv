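concentration,absorbance
0,0.004
25,0.262
50,0.517
100,1.021
200,2.043
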