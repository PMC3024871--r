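P1 R1 0 0 1 2 2 2 2 1 1 2 2 1 1 1 1 2 2 1 1 1 1 2 2 2 2 1 1
P2 R2 0 0 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1
P3 R3 0 0 1 1 1 2 2 1 1 2 2 1 1 2 2 1 1 1 1 2 2 2 2 1 1 2 2
P4 I1 0 0 1 1 2 1 2 1 1 1 2 1 1 1 1 1 2 1 1 1 1 1 2 1 2 1 1
P5 I2 0 0 1 1 2 2 2 1 1 2 2 1 1 1 2 1 2 1 1 1 2 2 2 1 2 1 2
P6 I3 0 0 1 1 1 1 2 1 1 1 2 1 1 1 2 1 1 1 1 1 2 1 2 1 1 1 2
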