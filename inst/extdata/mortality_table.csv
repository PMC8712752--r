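age,noncvd_male,noncvd_female,cvd_male,cvd_female
18,0.00666003,0.00602574,0.0191161,0.0191161
19,0.00693183,0.00627165,0.0191161,0.0191161
20,0.00721472,0.0065276,0.0191161,0.0191161
21,0.00750916,0.006794,0.0191161,0.0191161
22,0.00781561,0.00707127,0.0191161,0.0191161
23,0.00813457,0.00735985,0.0191161,0.0191161
24,0.00846655,0.00766021,0.0191161,0.0191161
25,0.00881208,0.00797283,0.0191161,0.0191161
26,0.00917171,0.00829821,0.0191161,0.0191161
27,0.00954601,0.00863687,0.0191161,0.0191161
28,0.00993559,0.00898934,0.0191161,0.0191161
29,0.0103411,0.00935621,0.0191161,0.0191161
30,0.0107631,0.00973804,0.0191161,0.0191161
31,0.0112023,0.0101355,0.0191161,0.0191161
32,0.0116595,0.0105491,0.0191161,0.0191161
33,0.0121354,0.0109796,0.0191161,0.0191161
34,0.0126306,0.0114277,0.0191161,0.0191161
35,0.0131461,0.0118941,0.0191161,0.0191161
36,0.0136826,0.0123795,0.0191161,0.0191161
37,0.014241,0.0128847,0.0191161,0.0191161
38,0.0148222,0.0134105,0.0191161,0.0191161
39,0.0154271,0.0139578,0.0191161,0.0191161
40,0.0160567,0.0145274,0.0191161,0.0191161
41,0.0167119,0.0151203,0.0191161,0.0191161
42,0.017394,0.0157374,0.0191161,0.0191161
43,0.0181038,0.0163797,0.0191161,0.0191161
44,0.0188427,0.0170481,0.0191161,0.0191161
45,0.0196116,0.0177439,0.0191161,0.0191161
46,0.020412,0.018468,0.0191161,0.0191161
47,0.021245,0.0192217,0.0191161,0.0191161
48,0.0221121,0.0200062,0.0191161,0.0191161
49,0.0230145,0.0208226,0.0191161,0.0191161
50,0.0239537,0.0216724,0.0191161,0.0191161
51,0.0249313,0.0225569,0.0191161,0.0191161
52,0.0259487,0.0234774,0.0191161,0.0191161
53,0.0270077,0.0244356,0.0191161,0.0191161
54,0.0281099,0.0254328,0.0191161,0.0191161
55,0.0292571,0.0264707,0.0191161,0.0191161
56,0.0304511,0.027551,0.0191161,0.0191161
57,0.0316939,0.0286754,0.0191161,0.0191161
58,0.0329873,0.0298457,0.0191161,0.0191161
59,0.0343336,0.0310637,0.0191161,0.0191161
60,0.0357347,0.0323314,0.0191161,0.0191161
61,0.0371931,0.0336509,0.0191161,0.0191161
62,0.038711,0.0350242,0.0191161,0.0191161
63,0.0402908,0.0364536,0.0191161,0.0191161
64,0.0419351,0.0379413,0.0191161,0.0191161
65,0.0436465,0.0394897,0.0191161,0.0191161
66,0.0454278,0.0411013,0.0191161,0.0191161
67,0.0472817,0.0427787,0.0191161,0.0191161
68,0.0492113,0.0445245,0.0191161,0.0191161
69,0.0512197,0.0463416,0.0191161,0.0191161
70,0.05331,0.0482328,0.0191161,0.0191161
71,0.0554856,0.0502012,0.0191161,0.0191161
72,0.05775,0.05225,0.0191161,0.0191161
73,0.0601068,0.0543824,0.0191161,0.0191161
74,0.0625598,0.0566017,0.0191161,0.0191161
75,0.0651129,0.0589117,0.0191161,0.0191161
76,0.0677703,0.0613159,0.0191161,0.0191161
77,0.070536,0.0638183,0.0191161,0.0191161
78,0.0734146,0.0664228,0.0191161,0.0191161
79,0.0764107,0.0691335,0.0191161,0.0191161
80,0.0795291,0.0719549,0.0191161,0.0191161
81,0.0827748,0.0748915,0.0191161,0.0191161
82,0.0861529,0.0779478,0.0191161,0.0191161
83,0.0896688,0.081129,0.0191161,0.0191161
84,0.0933283,0.0844399,0.0191161,0.0191161
85,0.0971371,0.0878859,0.0191161,0.0191161
86,0.101101,0.0914726,0.0191161,0.0191161
87,0.105227,0.0952057,0.0191161,0.0191161
88,0.109522,0.0990911,0.0191161,0.0191161
89,0.113991,0.103135,0.0191161,0.0191161
90,0.118644,0.107344,0.0191161,0.0191161
91,0.123485,0.111725,0.0191161,0.0191161
92,0.128525,0.116285,0.0191161,0.0191161
93,0.13377,0.12103,0.0191161,0.0191161
94,0.139229,0.12597,0.0191161,0.0191161
95,0.144912,0.13111,0.0191161,0.0191161
96,0.150825,0.136461,0.0191161,0.0191161
97,0.156981,0.14203,0.0191161,0.0191161
98,0.163387,0.147827,0.0191161,0.0191161
99,0.170055,0.15386,0.0191161,0.0191161
100,0.176995,0.160139,0.0191161,0.0191161
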