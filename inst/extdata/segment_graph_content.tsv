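a	b	omega
A1	B1	4.0
A2	B1	3.0
A3	B1	2.5
A3	B2	2.0
A4	B3	3.5
A4	B4	1.5
A5	B4	2.2
A5	B5	1.8
A4	B5	1.1
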