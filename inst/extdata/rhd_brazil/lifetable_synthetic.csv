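"age","expectancy"
0,71.5
1,70.7
2,69.9
3,69.1
4,68.3
5,67.5
6,66.7
7,65.9
8,65.1
9,64.3
10,63.5
11,62.7
12,61.9
13,61.1
14,60.3
15,59.5
16,58.7
17,57.9
18,57.1
19,56.3
20,55.5
21,54.7
22,53.9
23,53.1
24,52.3
25,51.5
26,50.7
27,49.9
28,49.1
29,48.3
30,47.5
31,46.7
32,45.9
33,45.1
34,44.3
35,43.5
36,42.7
37,41.9
38,41.1
39,40.3
40,39.5
41,38.7
42,37.9
43,37.1
44,36.3
45,35.5
46,34.7
47,33.9
48,33.1
49,32.3
50,31.5
51,30.7
52,29.9
53,29.1
54,28.3
55,27.5
56,26.7
57,25.9
58,25.1
59,24.3
60,23.5
61,22.7
62,21.9
63,21.1
64,20.3
65,19.5
66,18.7
67,17.9
68,17.1
69,16.3
70,15.5
71,14.7
72,13.9
73,13.1
74,12.3
75,11.5
76,10.7
77,9.9
78,9.09999999999999
79,8.3
80,7.5
81,6.7
82,5.89999999999999
83,5.09999999999999
84,4.3
85,3.5
86,2.7
87,2.5
88,2.5
89,2.5
90,2.5
91,2.5
92,2.5
93,2.5
94,2.5
95,2.5
96,2.5
97,2.5
98,2.5
99,2.5
100,2.5
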