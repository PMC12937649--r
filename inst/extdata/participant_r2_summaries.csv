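participant,p95_free,p95_fixed
1,0.92121,0.91043
2,0.80057,0.81403
4,0.89138,0.84567
5,0.79337,0.75863
6,0.90856,0.87141
7,0.92340,0.90599
8,0.93639,0.95328
10,0.88732,0.92721
11,0.87280,0.87551
12,0.85294,0.84348
14,0.92628,0.93512
15,0.81764,0.79053
16,0.87607,0.86314
17,0.91329,0.90465
18,0.91873,0.96464
20,0.85635,0.84248
21,0.86214,0.89940
22,0.86566,0.89024
23,0.88199,0.90425
24,0.89479,0.90496
25,0.84894,0.87096
26,0.89798,0.88680
27,0.77392,0.89827
28,0.66425,0.64146
29,0.82653,0.88260
31,0.82029,0.89407
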