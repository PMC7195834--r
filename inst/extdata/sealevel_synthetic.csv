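age,level
0,0
5,10
10,20
14,60
23,60
26,20
30,0
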