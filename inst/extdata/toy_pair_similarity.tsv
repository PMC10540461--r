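a	b	sigma
1	7	0.9
2	9	0.4
3	10	0.8
4	9	0.7
5	13	0.9
6	13	0.3
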