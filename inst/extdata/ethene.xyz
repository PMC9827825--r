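6
ethene, planar D2h geometry
C    0.00000000   0.00000000   0.66540000
C    0.00000000   0.00000000  -0.66540000
H    0.00000000   0.92290000   1.23700000
H    0.00000000  -0.92290000   1.23700000
H    0.00000000   0.92290000  -1.23700000
H    0.00000000  -0.92290000  -1.23700000
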