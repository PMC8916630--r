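candidate,true_pm
1,4.617
2,4.922
3,5.1227
4,5.2772
5,5.405
6,5.5151
7,5.6126
8,5.7007
9,5.7812
10,5.8558
11,5.9255
12,5.991
13,6.0529
14,6.1118
15,6.168
16,6.2218
17,6.2736
18,6.3234
19,6.3716
20,6.4183
21,6.4636
22,6.5076
23,6.5504
24,6.5922
25,6.633
26,6.6728
27,6.7118
28,6.7501
29,6.7876
30,6.8244
31,6.8605
32,6.896
33,6.931
34,6.9655
35,6.9994
36,7.0328
37,7.0659
38,7.0984
39,7.1306
40,7.1624
41,7.1938
42,7.2249
43,7.2557
44,7.2861
45,7.3163
46,7.3461
47,7.3757
48,7.4051
49,7.4342
50,7.463
51,7.4917
52,7.5201
53,7.5484
54,7.5764
55,7.6043
56,7.6319
57,7.6595
58,7.6868
59,7.714
60,7.7411
61,7.768
62,7.7948
63,7.8215
64,7.848
65,7.8745
66,7.9008
67,7.927
68,7.9532
69,7.9792
70,8.0052
71,8.0311
72,8.0569
73,8.0826
74,8.1083
75,8.1339
76,8.1594
77,8.1849
78,8.2103
79,8.2357
80,8.2611
81,8.2864
82,8.3117
83,8.3369
84,8.3621
85,8.3873
86,8.4125
87,8.4376
88,8.4628
89,8.4879
90,8.513
91,8.5381
92,8.5632
93,8.5883
94,8.6135
95,8.6386
96,8.6637
97,8.6889
98,8.7141
99,8.7393
100,8.7645
101,8.7897
102,8.815
103,8.8403
104,8.8656
105,8.891
106,8.9164
107,8.9419
108,8.9674
109,8.993
110,9.0186
111,9.0443
112,9.0701
113,9.0959
114,9.1217
115,9.1477
116,9.1737
117,9.1998
118,9.226
119,9.2522
120,9.2786
121,9.305
122,9.3315
123,9.3582
124,9.3849
125,9.4117
126,9.4387
127,9.4657
128,9.4929
129,9.5202
130,9.5476
131,9.5752
132,9.6029
133,9.6307
134,9.6586
135,9.6868
136,9.715
137,9.7434
138,9.772
139,9.8008
140,9.8297
141,9.8588
142,9.888
143,9.9175
144,9.9471
145,9.977
146,10.007
147,10.0373
148,10.0678
149,10.0985
150,10.1294
151,10.1606
152,10.192
153,10.2237
154,10.2556
155,10.2879
156,10.3203
157,10.3531
158,10.3862
159,10.4195
160,10.4532
161,10.4872
162,10.5216
163,10.5563
164,10.5913
165,10.6267
166,10.6625
167,10.6987
168,10.7353
169,10.7724
170,10.8099
171,10.8478
172,10.8862
173,10.9251
174,10.9644
175,11.0044
176,11.0448
177,11.0859
178,11.1275
179,11.1697
180,11.2126
181,11.2561
182,11.3004
183,11.3453
184,11.391
185,11.4375
186,11.4849
187,11.5331
188,11.5821
189,11.6322
190,11.6832
191,11.7353
192,11.7885
193,11.8429
194,11.8984
195,11.9553
196,12.0136
197,12.0733
198,12.1345
199,12.1974
200,12.262
201,12.3284
202,12.3969
203,12.4675
204,12.5404
205,12.6158
206,12.6938
207,12.7748
208,12.8589
209,12.9464
210,13.0377
211,13.1332
212,13.2333
213,13.3385
214,13.4494
215,13.5668
216,13.6916
217,13.8248
218,13.9677
219,14.1221
220,14.29
221,14.4744
222,14.679
223,14.9092
224,15.1728
225,15.4819
226,15.8568
227,16.335
228,17.0013
229,18.1244
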