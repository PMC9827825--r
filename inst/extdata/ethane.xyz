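8
ethane, staggered geometry
C    0.00000000   0.00000000   0.76560000
C    0.00000000   0.00000000  -0.76560000
H    1.01920000   0.00000000   1.16450000
H   -0.50960000   0.88260000   1.16450000
H   -0.50960000  -0.88260000   1.16450000
H   -1.01920000   0.00000000  -1.16450000
H    0.50960000  -0.88260000  -1.16450000
H    0.50960000   0.88260000  -1.16450000
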