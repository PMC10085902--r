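"field_index","count"
1,0
2,1
3,0
4,0
5,0
6,0
7,1
8,0
9,0
10,0
11,0
12,0
13,0
14,1
15,0
16,0
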