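elem1,elem2,order,energy_kJ
H,H,1,436
C,H,1,413
N,H,1,391
O,H,1,463
S,H,1,347
P,H,1,322
C,C,1,348
C,C,2,263
C,C,3,228
C,N,1,293
C,N,2,322
C,N,3,276
C,O,1,358
C,O,2,387
C,O,3,327
C,S,1,259
C,S,2,318
C,P,1,264
N,N,1,163
N,N,2,255
N,N,3,523
N,O,1,201
N,O,2,406
N,S,1,247
N,P,1,290
O,O,1,146
O,O,2,349
O,S,1,364
O,S,2,158
O,P,1,335
O,P,2,209
S,S,1,266
S,S,2,186
S,P,1,230
P,P,1,201
P,P,2,186
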