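R1	0201	0201
R2	0101	0101
R3	2401	2401
I1	0201	0101
I2	0201	2401
I3	-	-
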