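energy_keV,photoelectric_cm2_g,incoherent_cm2_g,coherent_cm2_g
5,39.70,0.0800,0.460
6,22.90,0.0920,0.405
8,9.480,0.1100,0.325
10,4.742,0.1340,0.243
15,1.334,0.1470,0.132
20,0.5240,0.1670,0.0866
30,0.1437,0.1650,0.0450
40,0.0566,0.1650,0.0270
50,0.0276,0.1620,0.0184
60,0.0152,0.1590,0.0131
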