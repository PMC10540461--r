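>A
c1	-6 1 8 9 -4
c2	3 -5 -7 2
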