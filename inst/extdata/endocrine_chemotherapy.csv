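value
1
1
1
3
3
1
1
18
4
5
6
6
4
5
5
9
15
24
4
2
5
5
7
1
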