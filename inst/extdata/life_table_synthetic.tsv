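age	annual_death_prob
40	0.001744026322
41	0.001870669097
42	0.002010193148
43	0.002163906586
44	0.002333249917
45	0.002519809344
46	0.002725331387
47	0.002951738946
48	0.003201148944
49	0.003475891692
50	0.003778532152
51	0.004111893251
52	0.004479081465
53	0.004883514838
54	0.005328953689
55	0.005819534223
56	0.006359805295
57	0.006954768603
58	0.007609922577
59	0.008331310275
60	0.009125571576
61	0.01
62	0.01096260448
63	0.01202217643
64	0.01318836235
65	0.01447174246
66	0.01588391548
67	0.01743758991
68	0.01914668197
69	0.02102642052
70	0.02309345872
71	0.02536599267
72	0.02786388661
73	0.03060880439
74	0.03362434643
75	0.0369361913
76	0.04057224045
77	0.04456276435
78	0.04894054747
79	0.05374102909
80	0.05900243601
81	0.06476590205
82	0.07107556837
83	0.07797865709
84	0.08552550923
85	0.09376957597
86	0.1027673508
87	0.1125782268
88	0.1232642631
89	0.1348898381
90	0.14752117
91	0.1612256766
92	0.1760711496
93	0.1921247127
94	0.2094515341
95	0.2281132646
96	0.2481661729
97	0.2696589573
98	0.2926302178
99	0.3171055882
100	0.3430945437
101	0.3705869228
102	0.3995492354
103	0.4299208646
104	0.4616103185
105	0.4944917372
106	0.5284019212
107	0.5631382002
108	0.5984575153
109	0.6340771217
110	0.6696773303
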