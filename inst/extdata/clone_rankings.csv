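clone,r5,r4,r3,r2,r1
40.25,1,1,1,1,1
42.14,2,2,2,3,3
35.21,3,3,7,24,120
32.34,4,4,6,22,9
65.13,5,7,9,18,49
15.07,6,8,10,21,72
10.24,7,5,3,3,2
21.54,8,6,4,4,9
34.19,9,9,5,7,12
40.03,10,10,8,6,8
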