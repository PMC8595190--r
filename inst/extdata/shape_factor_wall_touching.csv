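kappa,shape_factor,error_estimate
0.00000,1.000000000000,0.000000000e+00
0.03125,0.886175310565,1.359332528e-06
0.06250,0.791001991767,5.416481768e-08
0.09375,0.710158569007,1.835913964e-05
0.12500,0.640672305025,3.651807985e-05
0.15625,0.580236958376,1.399570339e-05
0.18750,0.527147628048,1.029511265e-06
0.21875,0.480109243383,8.597460957e-07
0.25000,0.438082433024,8.075217218e-05
0.28125,0.400360301051,3.255945440e-05
0.31250,0.366231468169,1.137078688e-05
0.34375,0.335186126527,1.183886674e-06
0.37500,0.306797866109,2.264363064e-06
0.40625,0.280692994096,1.368667861e-05
0.43750,0.256647726773,3.218666609e-05
0.46875,0.234359026885,1.314996370e-05
0.50000,0.213627310823,2.209899333e-06
0.53125,0.194258760644,9.317011546e-06
0.56250,0.176129803933,8.787437318e-05
0.59375,0.159097985914,2.075306918e-05
0.62500,0.143057338943,1.324544501e-05
0.65625,0.127881292887,4.044953040e-05
0.68750,0.113505597074,6.051423539e-06
0.71875,0.099834943323,4.482649019e-05
0.75000,0.086814573537,6.307512282e-05
0.78125,0.074386943705,2.720214666e-05
0.81250,0.062475769471,2.456076684e-04
0.84375,0.051075154403,5.533422829e-05
0.87500,0.040113911319,1.178129502e-05
0.90625,0.029554417139,3.840762262e-05
0.93750,0.019368115340,1.323980641e-05
0.96875,0.009525454673,2.071922860e-05
1.00000,0.000000000000,0.000000000e+00
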