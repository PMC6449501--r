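# SWC written by gcut
1 1 74.735063 120.672796 65.5419533 5 -1
2 3 75.2469868 123.522059 60.2865148 0.5 1
3 3 76.1730215 126.009171 54.9053688 0.5 2
4 3 75.942213 128.379467 49.398244 0.5 3
5 3 75.1636482 131.237524 44.1804525 0.5 4
6 3 75.7150545 134.555258 39.2116908 0.5 5
7 3 75.2293794 137.630994 34.0829516 0.5 6
8 3 74.965984 139.708151 28.4601369 0.5 7
9 3 69.3678433 118.700611 63.724417 0.5 1
10 3 64.4251494 116.367584 61.2491871 0.5 9
11 3 59.4042303 115.242404 58.163034 0.5 10
12 3 54.2991472 115.366813 55.0130105 0.5 11
13 3 49.6070021 114.874133 51.3061195 0.5 12
14 3 45.6030639 113.945709 46.9350202 0.5 13
15 3 40.6900937 113.0656 43.6051356 0.5 14
16 3 35.1484858 112.468307 41.3839146 0.5 15
17 3 29.2664729 112.402591 40.2017107 0.5 16
18 3 73.7305648 116.610123 61.2424563 0.5 1
19 3 71.4565295 112.725709 57.2750784 0.5 18
20 3 69.4076697 109.754079 52.4822097 0.5 19
21 3 67.2187155 107.94366 47.1972441 0.5 20
22 3 66.0522708 105.081882 42.0543234 0.5 21
23 3 64.7731858 103.0098 36.5706732 0.5 22
24 3 63.1169976 99.9041858 31.7114345 0.5 23
25 3 61.9216401 96.5215054 26.9022149 0.5 24
26 3 59.7407584 93.4438025 22.236221 0.5 25
27 3 57.9582252 90.9956256 17.0565487 0.5 26
28 3 23.6416661 114.450879 39.7941994 0.5 17
29 3 17.7016101 115.296006 39.8328688 0.5 28
30 3 11.7047559 115.149227 39.9601351 0.5 29
31 3 5.83008481 116.289787 39.5272813 0.5 30
32 3 0.154626748 117.182893 37.7976755 0.5 31
33 3 -5.03924284 119.09623 35.4818903 0.5 32
34 3 -10.3419856 120.592109 33.1063342 0.5 33
35 3 -15.1175364 122.60414 30.0821243 0.5 34
36 3 24.3690202 115.380264 38.4273307 0.5 17
37 3 19.7793706 119.050177 37.2161955 0.5 36
38 3 15.223376 122.742364 35.9470724 0.5 37
39 3 11.1179339 126.232787 33.3084569 0.5 38
40 3 6.00083587 128.540964 31.1900547 0.5 39
41 3 0.523302919 130.816982 30.2865218 0.5 40
42 3 -5.30505662 131.900966 29.3617492 0.5 41
43 3 57.3957514 86.0442776 13.7147263 0.5 27
44 3 56.8219884 80.8249636 10.8113564 0.5 43
45 3 55.5626751 75.3042701 8.82740245 0.5 44
46 3 54.5399283 69.5368363 7.52713469 0.5 45
47 3 54.7104622 63.8766782 5.54382199 0.5 46
48 3 53.5579711 58.376287 3.44204636 0.5 47
49 3 52.8316244 53.2061826 0.485284492 0.5 48
50 3 50.8569555 48.0608181 -1.88661488 0.5 49
51 3 47.9964966 43.7616543 -4.94193252 0.5 50
52 3 45.2104215 39.0763715 -7.44910436 0.5 51
53 3 42.0758489 34.9671421 -10.4968392 0.5 52
54 3 39.098297 30.897228 -13.7479905 0.5 53
55 3 58.7976265 87.6319891 12.1594725 0.5 27
56 3 59.326421 83.249634 8.09556547 0.5 55
57 3 58.789505 79.5404093 3.41012283 0.5 56
58 3 57.7700479 76.9658075 -1.91267092 0.5 57
59 3 57.0243165 75.4574553 -7.67190337 0.5 58
60 3 57.5982645 73.6677042 -13.3699183 0.5 59
61 3 57.1213923 71.0071729 -18.7266119 0.5 60
62 3 56.7556515 68.6193488 -24.2188364 0.5 61
63 3 55.5451766 66.6138181 -29.7426573 0.5 62
64 3 54.2671238 64.6214243 -35.256 0.5 63
65 3 52.5855475 62.9998731 -40.7825607 0.5 64
66 3 51.3511317 60.0896545 -45.8822514 0.5 65
67 1 134.892616 31.5685884 72.1776884 5 88
68 3 130.193262 34.8079649 70.3276852 0.5 67
69 3 125.496757 37.2311668 67.4867462 0.5 68
70 3 120.615554 40.3211125 65.8662248 0.5 69
71 3 116.426303 43.81143 63.3626548 0.5 70
72 3 112.513281 47.2864934 60.4280008 0.5 71
73 3 108.253496 51.1408249 58.6964225 0.5 72
74 3 103.161594 54.1501152 57.6881039 0.5 73
75 3 98.5314107 57.7973571 56.5660413 0.5 74
76 3 94.8795025 62.3665021 55.2294487 0.5 75
77 3 92.0413541 67.6063799 54.5304534 0.5 76
78 3 89.6061966 72.8866152 53.0508848 0.5 77
79 3 129.589451 34.3594018 72.4740104 0.5 67
80 3 124.402247 37.1327355 73.6578723 0.5 79
81 3 119.814373 40.964006 74.1801537 0.5 80
82 3 115.244026 44.762416 73.3531061 0.5 81
83 3 110.482173 47.8699203 71.437858 0.5 82
84 3 105.973604 51.6516966 70.2669707 0.5 83
85 3 101.837899 55.9961222 70.1189438 0.5 84
86 3 98.1710031 60.6179728 69.026987 0.5 85
87 3 93.7487571 64.6489379 68.5853305 0.5 86
88 3 130.35592 34.5750496 69.6519056 0.5 89
89 3 126.756398 38.3359184 66.6687344 0.5 90
90 3 123.438631 42.8977176 64.6236409 0.5 91
91 3 120.199926 46.8171809 61.4379543 0.5 92
92 3 116.982736 51.452325 59.3970897 0.5 93
93 3 113.521488 55.7953564 57.1260017 0.5 94
94 3 110.700535 60.6740797 55.0668067 0.5 95
95 3 107.942857 65.6970266 53.2877009 0.5 96
96 3 104.203698 70.2264677 52.0617934 0.5 97
97 3 99.7952993 74.2196499 51.2740639 0.5 98
98 3 94.6231003 77.1749324 50.5566639 0.5 118
99 3 91.4817292 78.5831384 53.2297737 0.5 78
100 3 93.6315087 84.1802467 53.455223 0.5 99
101 3 96.1947407 89.5347991 52.5842409 0.5 100
102 3 99.2263301 94.5411415 51.2628775 0.5 101
103 3 102.028461 99.5702278 49.5728022 0.5 102
104 3 104.875455 104.260146 47.1439555 0.5 103
105 3 108.11867 108.980759 45.3558371 0.5 104
106 3 111.573863 113.847467 44.7420072 0.5 105
107 3 88.6156611 77.7236187 49.6417447 0.5 78
108 3 87.7388042 82.7778155 46.5294758 0.5 107
109 3 86.8138289 87.0621576 42.432058 0.5 108
110 3 84.8546135 91.8739909 39.4307689 0.5 109
111 3 81.6585975 96.1327601 36.665201 0.5 110
112 3 77.7441064 100.297777 34.8405374 0.5 111
113 3 73.1453372 103.473878 32.6579472 0.5 112
114 3 68.78952 107.156028 30.7955206 0.5 113
115 3 64.1756091 109.872496 28.0876383 0.5 114
116 3 59.9199274 112.428164 24.7175147 0.5 115
117 3 56.7121078 115.249902 20.5047144 0.5 116
118 3 90.9577364 80.6975015 47.3697195 0.5 119
119 3 86.5731615 83.5529628 44.4334219 0.5 120
120 3 81.9964091 87.0396485 42.7315522 0.5 121
121 3 78.1422778 90.8169402 40.1090077 0.5 122
122 3 74.063637 93.570148 36.6761465 0.5 123
123 3 69.7056795 97.0793869 34.5097096 0.5 124
124 3 66.133648 100.594946 31.2110078 0.5 24
125 3 62.2971273 104.694751 29.0961301 0.5 124
126 3 59.5889431 109.443587 26.6234205 0.5 125
127 3 57.2656389 114.458484 24.2882399 0.5 126
128 3 54.0982839 119.403972 23.059414 0.5 127
129 3 88.8393359 78.6980295 51.0344133 0.5 98
130 3 83.2766009 80.3065683 52.6055856 0.5 129
131 3 77.6950158 82.1004566 53.8814664 0.5 130
132 3 72.2236245 84.42561 54.6923547 0.5 131
133 3 66.4391496 85.9476631 55.1647989 0.5 132
134 3 60.8930209 88.0069207 56.1647565 0.5 133
135 3 55.2732081 89.8674674 57.1425449 0.5 134
136 3 50.0500929 92.7012432 57.9724742 0.5 135
137 3 45.2030875 95.8199443 59.6398798 0.5 136
138 3 41.0114989 99.9067295 60.9547075 0.5 137
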