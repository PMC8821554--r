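subject,racc_left,racc_right,insula_left,insula_right,rolandic,inhibition
1,3.315,3.312,2.828,2.945,2.553,-10.15
2,2.71,2.712,3.306,2.948,2.632,22.88
3,3.042,3.134,2.758,2.371,2.645,28.65
4,2.656,2.651,2.97,3.348,2.855,88.42
5,2.839,2.915,3.409,2.722,2.477,80.88
6,2.513,2.521,3.216,2.907,2.83,83.5
7,3.317,3.22,3.099,2.818,2.384,-29.18
8,3.205,3.275,2.899,2.746,2.9,49.2
9,2.917,3.079,3.334,3.26,2.534,-11.87
10,3.062,3.042,2.826,3.169,2.522,17.77
11,2.828,2.795,3.549,2.729,2.782,46.87
12,2.45,2.586,2.599,2.794,2.727,17.89
13,2.739,2.635,3.041,3.001,2.662,60.18
14,3.088,3.125,2.517,2.851,2.555,45.76
15,2.646,2.55,2.935,2.515,2.699,92.24
16,2.577,2.558,2.678,3.133,2.119,48.29
17,2.529,2.648,3.126,3.173,2.558,62.54
18,3.204,3.218,2.527,3.042,3.179,11.25
19,2.883,2.942,3.151,2.989,2.551,-19.75
20,2.844,2.962,2.799,2.354,2.781,22.96
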