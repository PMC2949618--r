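age,sex,value
30,both,1.0960405687569284e-4
31,both,1.1873265737814868e-4
32,both,1.2862155224843021e-4
33,both,1.3933406417500346e-4
34,both,1.50938789807374e-4
35,both,1.635100390088371e-4
36,both,1.7712831069330125e-4
37,both,1.9188080829316527e-4
38,both,2.0786199815900388e-4
39,both,2.2517421446672495e-4
40,both,2.4392831450567075e-4
41,both,2.6424438854374315e-4
42,both,2.8625252881511385e-4
43,both,3.100936625546663e-4
44,both,3.359204544134325e-4
45,both,3.638982840335669e-4
46,both,3.9420630504267187e-4
47,both,4.270385922486563e-4
48,both,4.626053843810891e-4
49,both,5.011344303368371e-4
50,both,5.428724475505532e-4
51,both,5.880867018285663e-4
52,both,6.370667187625054e-4
53,both,6.90126137681542e-4
54,both,7.476047200148823e-4
55,both,8.098705249248801e-4
56,both,8.773222661422529e-4
57,both,9.503918650951907e-4
58,both,0.0010295472166811038
59,both,0.0011152951853913883
60,both,0.0012081848509746364
61,both,0.0013088110244216205
62,both,0.001417818056786356
63,both,0.0015359039652326992
64,both,0.0016638249027272722
65,both,0.0018024
66,both,0.0019525166107773454
67,both,0.0021151359938756387
68,both,0.0022912994685393
69,both,0.002482135082439129
70,both,0.0026888648350286257
71,both,0.002912812502512471
72,both,0.0031554121145336927
73,both,0.0034182171368592447
74,both,0.003702910418864543
75,both,0.0040113149695148245
76,both,0.004345405630846379
77,both,0.004707321723697828
78,both,0.005099380746667251
79,both,0.005524093216015308
80,both,0.005984178741540353
81,both,0.006482583441366073
82,both,0.007022498807155695
83,both,0.0076073821405545855
84,both,0.008240978691724228
85,both,0.008927345641729756
86,both,0.009670878082350247
87,both,0.010476337159671226
88,both,0.011348880561674447
89,both,0.012294095545049647
90,both,0.013318034712712604
91,both,0.014427254771127747
92,both,0.015628858515614533
93,both,0.016930540312486874
94,both,0.018340635369266577
95,both,0.01986817310846842
96,both,0.021522934986731225
97,both,0.023315517129534842
98,both,0.025257398182579067
99,both,0.02736101281430491
100,both,0.029639831340225332
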