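>B
c1	-6 1 2
c2	3 -5 -7 8 9 -4
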