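value
6
6
7
3
3
4
1
50
7
9
13
14
16
31
28
59
13
13
11
9
12
9
5
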