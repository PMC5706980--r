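no,term,estimate,se,statistic,p,pe_c3,p_c3,pe_c5,p_c5,pe_c7,p_c7,pe_c9,p_c9
1,Intercept,0.4812,0.1398,11.8569,0.0006,-1.1279,<.0001,-1.0087,<.0001,-0.8516,0.0512,-0.7417,0.5282
2,PT,-1.7191,0.1738,97.7837,<.0001,,,,,,,,
3,PT^2,0.6114,0.0506,145.981,<.0001,,,,,,,,
4,PT^3,-0.0854,0.0123,48.4214,<.0001,,,,,,,,
5,PT^4,0.00418,0.00076,30.2603,<.0001,,,,,,,,
6,Repetition,0.5968,0.0963,38.3929,<.0001,0.5968,<.0001,0.5968,<.0001,0.5968,<.0001,0.5968,<.0001
7,Manmade,-0.3262,0.1871,3.0397,0.0813,-0.6101,0.0156,-0.3264,0.2329,0.5248,0.2945,1.9435,0.0734
8,Manmade:PT,-0.2838,0.1522,3.4762,0.0623,,,,,,,,
9,Manmade:PT^2,0.0709,0.0325,4.7682,0.029,,,,,,,,
10,Symmetry,-0.9747,0.2245,18.8576,<.0001,-0.7251,0.019,-0.4044,0.0308,-0.0127,0.9773,0.45,0.7221
11,Symmetry:PT,0.107,0.1802,0.3528,0.5525,,,,,,,,
12,Symmetry:PT^2,0.00888,0.0421,0.0444,0.833,,,,,,,,
13,Manmade*Symmetry,0.8124,0.2637,9.4882,0.0021,0.7615,0.0165,0.2944,0.1873,-0.5891,0.1687,-1.8889,0.0903
14,Manmade*Symmetry:PT,0.0787,0.1465,0.2883,0.5913,,,,,,,,
15,Manmade*Symmetry:PT^2,-0.052,0.0352,2.1856,0.1393,,,,,,,,
16,Complex,-0.7629,0.1613,22.368,<.0001,-0.22,0.3533,-0.0593,0.8282,-0.2807,0.4455,-0.8842,0.2621
17,Complex:PT,0.367,0.1719,4.5583,0.0328,,,,,,,,
18,Complex:PT^2,-0.0478,0.0293,2.6635,0.1027,,,,,,,,
19,Complex*Manmade,0.2497,0.1094,5.2081,0.0225,0.4798,<.0001,0.7098,0.0039,0.9399,0.0201,1.17,0.0382
20,Complex*Manmade:PT,0.115,0.0809,2.0228,0.155,,,,,,,,
21,Complex*Symmetry,1.2609,0.1714,54.1072,<.0001,-0.1223,0.7041,-0.7979,0.0116,-0.7659,0.0088,-0.0264,0.975
22,Complex*Symmetry:PT,-0.8685,0.2245,14.9702,0.0001,,,,,,,,
23,Complex*Symmetry:PT^2,0.0884,0.0389,5.1704,0.023,,,,,,,,
24,Complex*Manmade*Symmetry,-1.292,0.2304,31.4403,<.0001,-0.0973,0.6591,1.0975,0.0008,2.2923,<.0001,3.4871,<.0001
25,Complex*Manmade*Symmetry:PT,0.5974,0.0888,45.2136,<.0001,,,,,,,,
26,MP,0.0926,0.2451,0.1428,0.7055,-0.3391,0.1621,-0.04,0.801,0.9901,0.0345,2.751,0.0231
27,MP:PT,-0.3986,0.1668,5.7112,0.0169,,,,,,,,
28,MP:PT^2,0.0914,0.0383,5.6875,0.0171,,,,,,,,
29,MP*Manmade,-0.3464,0.3001,1.3323,0.2484,-0.1232,0.632,0.1001,0.6737,0.3234,0.1913,0.5466,0.0537
30,MP*Manmade:PT,0.1116,0.0423,6.9592,0.0083,,,,,,,,
31,MP*Symmetry,-0.1032,0.1469,0.4939,0.4822,0.74,0.0002,0.3549,0.0447,-1.2584,0.0052,-4.1,0.0001
32,MP*Symmetry:PT,0.7287,0.147,24.5795,<.0001,,,,,,,,
33,MP*Symmetry:PT^2,-0.1535,0.0324,22.4171,0.0002,,,,,,,,
34,Complex*MP,-0.0189,0.1875,0.0102,0.9197,0.109,0.4256,0.2369,0.103,0.3648,0.0762,0.4927,0.0861
35,Complex*MP:PT,0.0639,0.0485,1.7371,0.1875,,,,,,,,
36,Complex*MP*Manmade,0.3601,0.1692,4.5279,0.0333,-0.07,0.7319,-0.5001,0.0738,-0.9301,0.0124,-1.3602,0.0039
37,Complex*MP*Manmade:PT,-0.215,0.0542,15.7596,0.0001,,,,,,,,
38,Patient,-2.4522,0.0966,644.4005,<.0001,-1.7005,<.0001,-1.7967,<.0001,-2.7408,<.0001,-4.5328,0.0002
39,Patient:PT,0.5878,0.191,9.4702,0.0021,,,,,,,,
40,Patient:PT^2,-0.106,0.0423,6.2656,0.0123,,,,,,,,
41,Manmade*Patient,0.0988,0.1125,0.77,0.3802,1.0101,<.0001,1.4338,<.0001,1.3697,<.0001,0.8178,0.3841
42,Manmade*Patient:PT,0.5776,0.1282,20.3075,<.0001,,,,,,,,
43,Manmade*Patient:PT^2,-0.061,0.031,3.8586,0.0495,,,,,,,,
44,Patient*Symmetry,-0.5621,0.1481,14.4003,0.0001,-0.6621,0.0185,-0.2908,0.0699,0.5518,0.2039,1.8658,0.1447
45,Patient*Symmetry:PT,-0.1678,0.1878,0.7992,0.3713,,,,,,,,
46,Patient*Symmetry:PT^2,0.0589,0.044,1.7948,0.1803,,,,,,,,
47,Manmade*Patient*Symmetry,0.8693,0.2014,18.6388,<.0001,-0.7167,0.0099,-1.5404,<.0001,-1.6017,<.0001,-0.9007,0.372
48,Manmade*Patient*Symmetry:PT,-0.9836,0.1265,60.4669,<.0001,,,,,,,,
49,Manmade*Patient*Symmetry:PT^2,0.0953,0.0317,9.0246,0.0027,,,,,,,,
50,Complex*Patient,0.5244,0.0871,36.2648,<.0001,-0.6399,0.0029,-0.6238,0.0093,0.5728,0.044,2.9498,<.0001
51,Complex*Patient:PT,-0.8772,0.164,28.6032,<.0001,,,,,,,,
52,Complex*Patient:PT^2,0.1476,0.0288,26.2467,<.0001,,,,,,,,
53,Complex*Patient*Symmetry,-0.3681,0.109,11.4144,0.0007,1.2133,<.0001,0.8155,<.0001,-1.5614,<.0001,-5.9176,<.0001
54,Complex*Patient*Symmetry:PT,1.2855,0.2309,30.9987,<.0001,,,,,,,,
55,Complex*Patient*Symmetry:PT^2,-0.2474,0.0435,32.3873,<.0001,,,,,,,,
56,MP*Patient,0.0131,0.0836,0.0246,0.8754,0.3665,0.0237,-0.2272,0.0008,-1.7681,0.0004,-4.2562,0.001
57,MP*Patient:PT,0.4135,0.162,6.5149,0.0107,,,,,,,,
58,MP*Patient:PT^2,-0.1184,0.0398,8.8388,0.0029,,,,,,,,
59,MP*Patient*Symmetry,0.2481,0.1216,4.1629,0.0413,-0.1751,0.3393,0.4794,0.0068,2.2117,<.0001,5.0216,<.0001
60,MP*Patient*Symmetry:PT,-0.481,0.1711,7.904,0.0049,,,,,,,,
61,MP*Patient*Symmetry:PT^2,0.1347,0.0368,13.4281,0.0002,,,,,,,,
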