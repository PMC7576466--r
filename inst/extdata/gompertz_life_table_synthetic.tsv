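age	sex	qx
0	F	1.15687340700443e-05
1	F	1.27854206750655e-05
2	F	1.41300656054666e-05
3	F	1.56161259742271e-05
4	F	1.72584741072734e-05
5	F	1.90735463635461e-05
6	F	2.10795076028836e-05
7	F	2.32964329462959e-05
8	F	2.57465086460629e-05
9	F	2.84542540732735e-05
10	F	3.14467670436969e-05
11	F	3.47539949328013e-05
12	F	3.8409034291198e-05
13	F	4.24484619533372e-05
14	F	4.69127009491421e-05
15	F	5.18464248738804e-05
16	F	5.72990047558175e-05
17	F	6.33250028827526e-05
18	F	6.99847185205993e-05
19	F	7.73447909691027e-05
20	F	8.54788659736538e-05
21	F	9.44683321413287e-05
22	F	0.000104403134705278
23	F	0.000115382674748088
24	F	0.00012751680284806
25	F	0.000140926917041817
26	F	0.000155747176034948
27	F	0.000172125839732251
28	F	0.000190226750414912
29	F	0.000210230969283964
30	F	0.000232338584617575
31	F	0.000256770709480714
32	F	0.000283771688786016
33	F	0.000313611537559155
34	F	0.000346588634520195
35	F	0.000383032697587216
36	F	0.000423308070649275
37	F	0.000467817353977606
38	F	0.000517005413964045
39	F	0.00057136381153311
40	F	0.000631435692587168
41	F	0.00069782118825823
42	F	0.000771183377583973
43	F	0.000852254870534974
44	F	0.000941845075146386
45	F	0.0010408482188814
46	F	0.00115025220132758
47	F	0.0012711483629454
48	F	0.00140474226290188
49	F	0.00155236556807481
50	F	0.00171548916516029
51	F	0.00189573761850392
52	F	0.00209490510784593
53	F	0.00231497299267125
54	F	0.00255812916331399
55	F	0.00282678935341141
56	F	0.00312362060374105
57	F	0.00345156708390171
58	F	0.00381387849567394
59	F	0.00421414130016029
60	F	0.0046563130298376
61	F	0.00514475996630159
62	F	0.00568429848450502
63	F	0.00628024038436537
64	F	0.00693844255032527
65	F	0.0076653612982126
66	F	0.0084681117858485
67	F	0.00935453287835042
68	F	0.0103332578697823
69	F	0.0114137914682447
70	F	0.0126065934497823
71	F	0.0139231693753408
72	F	0.0153761687415658
73	F	0.0169794908970208
74	F	0.0187483989961945
75	F	0.0206996421792834
76	F	0.0228515860500504
77	F	0.0252243513696113
78	F	0.0278399606820159
79	F	0.0307224923275798
80	F	0.0338982409698519
81	F	0.0373958833477898
82	F	0.0412466474498168
83	F	0.0454844826725499
84	F	0.0501462277533197
85	F	0.0552717723295894
86	F	0.0609042068554513
87	F	0.0670899542703337
88	F	0.0738788752427398
89	F	0.0813243369790182
90	F	0.0894832334755262
91	F	0.0984159426915262
92	F	0.108186203432992
93	F	0.118860891787247
94	F	0.1305096737868
95	F	0.14320450770042
96	F	0.157018966096257
97	F	0.172027344813617
98	F	0.188303523524574
99	F	0.205919541085471
100	F	0.224943848927174
101	F	0.245439208024442
102	F	0.267460200402409
103	F	0.291050335738888
104	F	0.316238748618219
105	F	0.343036503700586
106	F	0.371432555807865
107	F	0.401389450842509
108	F	0.432838902273286
109	F	0.465677436577696
110	F	1
0	M	1.89305860678335e-05
1	M	2.09215123573303e-05
2	M	2.31218215813733e-05
3	M	2.5553533714695e-05
4	M	2.82409843664899e-05
5	M	3.1211068268755e-05
6	M	3.4493508359601e-05
7	M	3.81211531543801e-05
8	M	4.21303053733668e-05
9	M	4.65610851133613e-05
10	M	5.14578311880953e-05
11	M	5.68695446483414e-05
12	M	6.28503789110724e-05
13	M	6.94601813904239e-05
14	M	7.67650920383556e-05
15	M	8.48382047662355e-05
16	M	9.37602983482888e-05
17	M	0.000103620644093638
18	M	0.000114517898340716
19	M	0.000126561088666821
20	M	0.000139870703635525
21	M	0.00015457989693235
22	M	0.000170835817868031
23	M	0.000188801081481005
24	M	0.000208655392846091
25	M	0.000230597341718597
26	M	0.000254846385318586
27	M	0.000281645038907707
28	M	0.000311261295850795
29	M	0.000343991301094748
30	M	0.00038016230447746
31	M	0.000420135922995502
32	M	0.000464311744162949
33	M	0.000513131305890702
34	M	0.000567082491943038
35	M	0.000626704386017307
36	M	0.000692592631873712
37	M	0.000765405351750181
38	M	0.000845869680576317
39	M	0.000934788979279233
40	M	0.00103305079681137
41	M	0.0011416356574524
42	M	0.00126162675751107
43	M	0.00139422066380579
44	M	0.00154073911530328
45	M	0.00170264203907966
46	M	0.0018815419023861
47	M	0.00207921953411239
48	M	0.00229764156136036
49	M	0.00253897962023497
50	M	0.002805631514323
51	M	0.00310024450969892
52	M	0.00342574097164916
53	M	0.00378534656560936
54	M	0.0041826212630155
55	M	0.00462149341174167
56	M	0.00510629715041377
57	M	0.0056418134658851
58	M	0.00623331521324688
59	M	0.00688661643750088
60	M	0.00760812635487307
61	M	0.00840490836901231
62	M	0.0092847445120412
63	M	0.0102562057114718
64	M	0.0113287282898916
65	M	0.0125126971032218
66	M	0.0138195357130085
67	M	0.0152618039658036
68	M	0.0168533033147997
69	M	0.0186091901613505
70	M	0.0205460974117163
71	M	0.0226822643312851
72	M	0.0250376746272802
73	M	0.0276342024928877
74	M	0.0304957660905955
75	M	0.0336484876282007
76	M	0.0371208587735125
77	M	0.0409439096470662
78	M	0.0451513790078952
79	M	0.0497798824850803
80	M	0.0548690747847581
81	M	0.0604618006943339
82	M	0.0666042283874145
83	M	0.0733459569793674
84	M	0.0807400884709111
85	M	0.0888432521269671
86	M	0.097715566958848
87	M	0.107420525311721
88	M	0.118024777627433
89	M	0.129597795304499
90	M	0.142211385301338
91	M	0.155939026867043
92	M	0.170854997747753
93	M	0.187033254706814
94	M	0.204546031624634
95	M	0.223462118355427
96	M	0.24384478561206
97	M	0.265749326298109
98	M	0.289220192951684
99	M	0.314287725511762
100	M	0.340964484774308
101	M	0.369241235995275
102	M	0.399082665290006
103	M	0.430422959540793
104	M	0.463161438467329
105	M	0.497158494121553
106	M	0.532232165319825
107	M	0.568155746952139
108	M	0.604656898161541
109	M	0.641418756985646
110	M	1
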