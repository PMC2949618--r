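age,sex,value
30,both,4.0109590747549614e-4
31,both,4.3886882725909226e-4
32,both,4.801989847067631e-4
33,both,5.254213801274916e-4
34,both,5.749025622444012e-4
35,both,6.29043599244058e-4
36,both,6.882833296222144e-4
37,both,7.531019191756237e-4
38,both,8.240247529710075e-4
39,both,9.016266938374148e-4
40,both,9.8653674189905e-4
41,both,0.0010794431329162653
42,both,0.001181098916759163
43,both,0.0012923280612299568
44,both,0.0014140321307084312
45,both,0.0015471975937540502
46,both,0.0016929038188962628
47,both,0.0018523318234226337
48,both,0.0020267738460778262
49,both,0.0022176438212646596
50,both,0.002426488839645545
51,both,0.002655001688037851
52,both,0.00290503457024494
53,both,0.00317861412003663
54,both,0.003477957827966348
55,both,0.0038054920151720083
56,both,0.0041638714998467295
57,both,0.004556001115785335
58,both,0.004985059257424557
59,both,0.005454523642220543
60,both,0.005968199499179799
61,both,0.0065302504120248505
62,both,0.0071452320669929455
63,both,0.007818129178809505
64,both,0.008554395894138696
65,both,0.00936
66,both,0.01024147129548077
67,both,0.011205954518820144
68,both,0.012261267258863196
69,both,0.013415963320284784
70,both,0.014679402056187979
71,both,0.016061824230050276
72,both,0.01757443502191425
73,both,0.01922949485162679
74,both,0.021040418755291772
75,both,0.023021885120429048
76,both,0.025189954661189094
77,both,0.027562200597973308
78,both,0.030157851096626758
79,both,0.03299794512173998
80,both,0.03610550296732368
81,both,0.03950571284708773
82,both,0.043226135056725956
83,both,0.04729692536303779
84,both,0.05175107943056068
85,both,0.056624700266905165
86,both,0.0619572908545632
87,both,0.06779207434110708
88,both,0.07417634438307119
89,both,0.08116184848321795
90,both,0.08880520742831581
91,both,0.09716837422717005
92,both,0.1063191362688136
93,both,0.11633166477108581
94,both,0.12728711597313747
95,both,0.1392742889448097
96,both,0.1523903453447397
97,both,0.16674159696117016
98,both,0.18244436741885123
99,both,0.1996259350365718
100,both,0.2184255644776238
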