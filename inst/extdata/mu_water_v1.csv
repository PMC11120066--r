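energy_keV,photoelectric_cm2_g,incoherent_cm2_g,coherent_cm2_g
5,41.10,0.0840,0.482
6,23.17,0.0969,0.421
8,9.915,0.1171,0.340
10,4.944,0.1347,0.251
15,1.374,0.1620,0.1365
20,0.5437,0.1774,0.0886
30,0.1466,0.1830,0.0459
40,0.0577,0.1830,0.0277
50,0.0277,0.1805,0.0187
60,0.0153,0.1765,0.0134
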