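haplogroup	count
A	9
B	7
C	4
D	4
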