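wavelength,reflectance
350,0.050
400,0.048
450,0.050
500,0.062
550,0.120
600,0.085
650,0.055
680,0.048
700,0.100
720,0.250
750,0.420
800,0.460
900,0.470
1000,0.462
1100,0.452
1200,0.435
1300,0.420
1400,0.300
1450,0.240
1500,0.300
1650,0.330
1800,0.310
1900,0.150
1940,0.100
2000,0.140
2100,0.180
2200,0.190
2300,0.170
2400,0.130
2500,0.100
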