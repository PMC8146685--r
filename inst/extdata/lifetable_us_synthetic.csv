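# Synthetic Gompertz-Makeham period life table (both sexes, all causes).
# Generated by gepnetcea::synth_life_table(a = 6.4e-5, b = 0.085, c = 5e-4, 0, 100);
# calibrated to approximate contemporary US all-cause mortality at ages 60+
# (q60 ~ 0.011, e60 ~ 21.6 y). NOT a published national table.
age,qx
0,0.00056663813
1,0.00057256094
2,0.00057900917
3,0.00058602942
4,0.00059367243
5,0.00060199343
6,0.00061105257
7,0.00062091532
8,0.00063165295
9,0.00064334307
10,0.00065607014
11,0.00066992613
12,0.00068501117
13,0.00070143425
14,0.00071931403
15,0.00073877969
16,0.00075997185
17,0.00078304361
18,0.00080816162
19,0.00083550731
20,0.00086527818
21,0.00089768922
22,0.00093297448
23,0.00097138873
24,0.0010132093
25,0.0010587381
26,0.0011083037
27,0.0011622638
28,0.0012210078
29,0.0012849594
30,0.00135458
31,0.0014303716
32,0.0015128807
33,0.001602702
34,0.0017004828
35,0.0018069275
36,0.0019228028
37,0.0020489429
38,0.0021862557
39,0.002335729
40,0.0024984376
41,0.0026755511
42,0.0028683418
43,0.003078194
44,0.0033066135
45,0.0035552381
46,0.0038258495
47,0.0041203851
48,0.0044409521
49,0.0047898415
50,0.0051695444
51,0.0055827686
52,0.0060324578
53,0.0065218108
54,0.0070543039
55,0.0076337136
56,0.0082641425
57,0.0089500459
58,0.0096962612
59,0.01050804
60,0.01139108
61,0.012351566
62,0.013396201
63,0.014532258
64,0.015767615
65,0.017110808
66,0.018571081
67,0.020158439
68,0.021883704
69,0.023758575
70,0.025795693
71,0.028008706
72,0.030412335
73,0.033022449
74,0.035856136
75,0.038931779
76,0.042269129
77,0.045889384
78,0.049815259
79,0.054071061
80,0.058682756
81,0.063678026
82,0.069086327
83,0.074938923
84,0.081268916
85,0.088111248
86,0.095502684
87,0.10348176
88,0.11208871
89,0.12136531
90,0.13135475
91,0.14210133
92,0.1536502
93,0.16604695
94,0.17933714
95,0.19356569
96,0.20877621
97,0.22501015
98,0.24230582
99,0.26069734
100,1
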