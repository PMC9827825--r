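water O
methane C
ethane CC
ethene C=C
ethanol CCO
hydrogen_peroxide OO
formaldehyde C=O
khp O=CCCOO
propylene_carbonate CC1COC(=O)O1
methyl_butanoate CCCC(=O)OC
glucose_open_chain OCC(O)C(O)C(O)C(O)C=O
butadiene C=CC=C
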