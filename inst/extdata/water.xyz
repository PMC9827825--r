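3
water, equilibrium-like geometry
O    0.00000000   0.00000000   0.11779000
H    0.00000000   0.75545000  -0.47116000
H    0.00000000  -0.75545000  -0.47116000
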