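element	radius
C	1.87
N	1.65
O	1.4
S	1.85
P	1.8
H	1.1
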