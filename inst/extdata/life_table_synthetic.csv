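"age","sex","annual_qx"
0,"female",0.000129490758248085
1,"female",0.00013056339737938
2,"female",0.000131757172858404
3,"female",0.000133085764805307
4,"female",0.000134564398217574
5,"female",0.000136210017420813
6,"female",0.000138041480217566
7,"female",0.000140079773955359
8,"female",0.000142348255991243
9,"female",0.000144872921303163
10,"female",0.000147682700314622
11,"female",0.00015080979033999
12,"female",0.000154290024446779
13,"female",0.000158163281954615
14,"female",0.000162473945269692
15,"female",0.000167271408280878
16,"female",0.000172610642135029
17,"female",0.000178552824860012
18,"female",0.000185166042037554
19,"female",0.000192526066535414
20,"female",0.000200717226209179
21,"female",0.000209833369489987
22,"female",0.000219978939884347
23,"female",0.000231270171656139
24,"female",0.000243836420334986
25,"female",0.000257821643229406
26,"female",0.000273386046822699
27,"female",0.000290707919825883
28,"female",0.000309985672757418
29,"female",0.000331440107260939
30,"female",0.000355316940960804
31,"female",0.000381889616537179
32,"female",0.000411462426899489
33,"female",0.000444373991882907
34,"female",0.000481001125829605
35,"female",0.00052176313978114
36,"female",0.000567126626847214
37,"female",0.000617610784675815
38,"female",0.000673793334889039
39,"female",0.000736317105919704
40,"female",0.000805897352951779
41,"female",0.000883329896702811
42,"female",0.000969500171658311
43,"female",0.001065393284157
44,"female",0.00117210519151434
45,"female",0.00129085512525096
46,"female",0.00142299939454638
47,"female",0.00157004672037298
48,"female",0.00173367526646773
49,"female",0.00191575155047163
50,"female",0.00211835143730088
51,"female",0.00234378343719899
52,"female",0.00259461455302989
53,"female",0.00287369894526968
54,"female",0.00318420970887279
55,"female",0.0035296740837345
56,"female",0.00391401244978318
57,"female",0.00434158148872432
58,"female",0.00481722192690914
59,"female",0.00534631130742658
60,"female",0.00593482227386477
61,"female",0.00658938688264177
62,"female",0.00731736749450596
63,"female",0.00812693482762328
64,"female",0.00902715378309615
65,"female",0.0100280776768504
66,"female",0.011140851527077
67,"female",0.0123778250506326
68,"female",0.0137526760109481
69,"female",0.0152805445290159
70,"female",0.0169781789116055
71,"female",0.0188640934592035
72,"female",0.0209587385806781
73,"female",0.0232846833506133
74,"female",0.0258668103844142
75,"female",0.0287325225585203
76,"female",0.0319119606479087
77,"female",0.0354382303662659
78,"female",0.0393476365473644
79,"female",0.0436799212663673
80,"female",0.0484785015294111
81,"female",0.0537907007168849
82,"female",0.0596679662039876
83,"female",0.0661660634526715
84,"female",0.0733452343219763
85,"female",0.0812703043319066
86,"female",0.090010720100091
87,"female",0.0996404941259724
88,"female",0.110238029526305
89,"female",0.121885792270157
90,"female",0.134669793023656
91,"female",0.148678835082033
92,"female",0.164003479343484
93,"female",0.180734672326774
94,"female",0.198961979514852
95,"female",0.218771364732461
96,"female",0.24024245805221
97,"female",0.26344526142772
98,"female",0.2884362547972
99,"female",0.315253888055845
100,"female",0.34391347858894
0,"male",0.000221031151706685
1,"male",0.000223291670963577
2,"male",0.000225794926662526
3,"male",0.00022856698333551
4,"male",0.000231636704109528
5,"male",0.000235036051159598
6,"male",0.000238800418410956
7,"male",0.000242968999948023
8,"male",0.000247585197961642
9,"male",0.000252697074473618
10,"male",0.00025835785153383
11,"male",0.000264626465087292
12,"male",0.00027156817826357
13,"male",0.000279255260458577
14,"male",0.000287767739258427
15,"male",0.000297194233009224
16,"male",0.000307632872671326
17,"male",0.000319192322517647
18,"male",0.00033199291025765
19,"male",0.000346167878295445
20,"male",0.000361864769082176
21,"male",0.000379246958896795
22,"male",0.000398495355922623
23,"male",0.000419810280167132
24,"male",0.000443413544639615
25,"male",0.000469550759259252
26,"male",0.000498493881241346
27,"male",0.000530544038218617
28,"male",0.000566034653131653
29,"male",0.000605334902975874
30,"male",0.000648853546872941
31,"male",0.000697043162654065
32,"male",0.000750404835241025
33,"male",0.000809493344634316
34,"male",0.000874922906286102
35,"male",0.00094737352210883
36,"male",0.00102759800638541
37,"male",0.00111642975745163
38,"male",0.00121479135327052
39,"male",0.00132370405696636
40,"male",0.00144429832708115
41,"male",0.00157782543683238
42,"male",0.00172567031703186
43,"male",0.00188936574864051
44,"male",0.00207060804324255
45,"male",0.00227127436307251
46,"male",0.00249344184668776
47,"male",0.00273940872196576
48,"male",0.0030117176048815
49,"male",0.0033131812004713
50,"male",0.00364691064152811
51,"male",0.00401634672085083
52,"male",0.00442529429420957
53,"male",0.00487796015345732
54,"male",0.00537899469222525
55,"male",0.00593353771008387
56,"male",0.00654726872456524
57,"male",0.00722646218347223
58,"male",0.00797804799177348
59,"male",0.0088096777871719
60,"male",0.00972979741499569
61,"male",0.0107477260648887
62,"male",0.0118737425370226
63,"male",0.0131191791018518
64,"male",0.0144965234018894
65,"male",0.0160195288129765
66,"male",0.0177033336316351
67,"male",0.0195645893789202
68,"male",0.0216215984031713
69,"male",0.0238944608162633
70,"male",0.0264052306008964
71,"male",0.0291780804688353
72,"male",0.0322394747184089
73,"male",0.0356183489184072
74,"male",0.039346294716509
75,"male",0.0434577474127279
76,"male",0.0479901731284317
77,"male",0.0529842514129255
78,"male",0.0584840479337863
79,"male",0.0645371704636706
80,"male",0.0711948996742285
81,"male",0.0785122842474509
82,"male",0.0865481874905012
83,"male",0.0953652699743596
84,"male",0.105029889705142
85,"male",0.1156118979971
86,"male",0.127184305596164
87,"male",0.139822789795167
88,"male",0.153605009439748
89,"male",0.168609691081822
90,"male",0.184915446433859
91,"male",0.202599279183226
92,"male",0.221734738771904
93,"male",0.242389680751863
94,"male",0.264623598818007
95,"male",0.288484503842711
96,"male",0.314005341633436
97,"male",0.341199965293908
98,"male",0.370058711603247
99,"male",0.400543675173803
100,"male",0.432583830260622
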