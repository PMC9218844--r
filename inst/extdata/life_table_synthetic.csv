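age,qx_female,qx_male
0,0.00015896,0.000229
1,0.00015996,0.0002319
2,0.000161071,0.000235089
3,0.000162307,0.000238598
4,0.00016368,0.000242457
5,0.000165207,0.000246702
6,0.000166904,0.000251372
7,0.000168791,0.000256509
8,0.000170888,0.000262159
9,0.000173219,0.000268374
10,0.00017581,0.000275211
11,0.000178691,0.000282731
12,0.000181892,0.000291003
13,0.000185452,0.000300103
14,0.000189408,0.000310112
15,0.000193806,0.000321122
16,0.000198695,0.000333233
17,0.000204129,0.000346554
18,0.00021017,0.000361208
19,0.000216885,0.000377327
20,0.000224349,0.000395058
21,0.000232646,0.000414561
22,0.00024187,0.000436015
23,0.000252122,0.000459614
24,0.000263519,0.000485572
25,0.000276188,0.000514127
26,0.00029027,0.000545536
27,0.000305924,0.000580085
28,0.000323325,0.00061809
29,0.000342668,0.000659894
30,0.00036417,0.000705878
31,0.000388071,0.00075646
32,0.00041464,0.0008121
33,0.000444174,0.000873303
34,0.000477003,0.000940626
35,0.000513497,0.00101468
36,0.000554063,0.00109614
37,0.000599156,0.00118574
38,0.000649282,0.00128431
39,0.000705001,0.00139272
40,0.000766939,0.00151198
41,0.000835789,0.00164317
42,0.000912323,0.00178747
43,0.000997398,0.0019462
44,0.00109197,0.0021208
45,0.00119709,0.00231286
46,0.00131394,0.00252412
47,0.00144384,0.0027565
48,0.00158823,0.00301213
49,0.00174874,0.00329331
50,0.00192716,0.0036026
51,0.00212549,0.00394282
52,0.00234595,0.00431707
53,0.00259102,0.00472873
54,0.00286343,0.00518155
55,0.00316625,0.00567965
56,0.00350286,0.00622755
57,0.00387704,0.00683024
58,0.00429298,0.00749319
59,0.00475533,0.00822242
60,0.00526929,0.00902458
61,0.0058406,0.00990693
62,0.00647566,0.0108775
63,0.0071816,0.0119452
64,0.00796633,0.0131195
65,0.00883863,0.0144113
66,0.00980827,0.0158323
67,0.0108861,0.0173954
68,0.0120843,0.0191147
69,0.0134161,0.021006
70,0.0148966,0.0230863
71,0.0165424,0.0253747
72,0.0183717,0.0278919
73,0.0204053,0.0306608
74,0.0226657,0.0337065
75,0.0251785,0.0370568
76,0.0279717,0.0407421
77,0.0310765,0.0447958
78,0.0345279,0.0492549
79,0.0383645,0.0541599
80,0.0426292,0.0595552
81,0.0473699,0.0654901
82,0.0526396,0.0720184
83,0.0584974,0.0791994
84,0.065009,0.0870985
85,0.0722472,0.0957874
86,0.0802932,0.105345
87,0.0892371,0.115858
88,0.0991792,0.127423
89,0.110231,0.140144
90,0.122516,0.154137
91,0.136172,0.169528
92,0.151352,0.186459
93,0.168226,0.205083
94,0.186983,0.225569
95,0.207833,0.248104
96,0.231011,0.272891
97,0.256775,0.300157
98,0.285414,0.33015
99,0.317249,0.363141
100,0.352637,0.399431
101,0.391975,0.43935
102,0.435702,0.48326
103,0.48431,0.53156
104,0.538342,0.584691
105,0.598404,0.643133
106,0.665169,0.707419
107,0.739384,0.778133
108,0.821883,0.855918
109,0.913587,0.94148
110,1,1
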