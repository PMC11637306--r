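# SWC written by axonwave
1 2 0 0 0 0.15 -1
2 2 2 0 0 0.15 1
3 2 4 0 0 0.15 2
4 2 6 0 0 0.15 3
5 2 8 0 0 0.15 4
6 2 10 0 0 0.15 5
7 2 12 0 0 0.15 6
8 2 14 0 0 0.15 7
9 2 16 0 0 0.15 8
10 2 18 0 0 0.15 9
11 2 20 0 0 0.15 10
12 2 22 0 0 0.15 11
13 2 24 0 0 0.15 12
14 2 26 0 0 0.15 13
15 2 28 0 0 0.15 14
16 2 30 0 0 0.15 15
17 2 32 0 0 0.15 16
18 2 34 0 0 0.15 17
19 2 36 0 0 0.15 18
20 2 38 0 0 0.184376358 19
21 2 40 0 0 0.156052038 20
22 2 42 0 0 0.15 21
23 2 44 0 0 0.15 22
24 2 46 0 0 0.15 23
25 2 48 0 0 0.15 24
26 2 50 0 0 0.15 25
27 2 52 0 0 0.15 26
28 2 54 0 0 0.15 27
29 2 56 0 0 0.15 28
30 2 58 0 0 0.150000092 29
31 2 60 0 0 0.163408892 30
32 5 62 0 0 1.40929295 31
33 5 64 0 0 0.225999907 32
34 2 66 0 0 0.150002947 33
35 2 68 0 0 0.15 34
36 2 70 0 0 0.15 35
37 2 72 0 0 0.15 36
38 2 74 0 0 0.15 37
39 2 76 0 0 0.15 38
40 2 78 0 0 0.15 39
41 2 80 0 0 0.15 40
42 2 82 0 0 0.15 41
43 2 84 0 0 0.15000087 42
44 5 86 0 0 0.697023196 43
45 2 88 0 0 0.150004778 44
46 2 90 0 0 0.15 45
47 2 92 0 0 0.15 46
48 2 94 0 0 0.15 47
49 2 96 0 0 0.15 48
50 2 98 0 0 0.15 49
51 2 100 0 0 0.15 50
52 2 102 0 0 0.15 51
53 2 104 0 0 0.15 52
54 2 106 0 0 0.150002098 53
55 2 108 0 0 0.172587303 54
56 5 110 0 0 1.45925543 55
57 5 112 0 0 0.558523744 56
58 2 114 0 0 0.150686188 57
59 2 116 0 0 0.150000006 58
60 2 118 0 0 0.15 59
61 2 120 0 0 0.15 60
62 2 122 0 0 0.15 61
63 2 124 0 0 0.15 62
64 2 126 0 0 0.15 63
65 2 128 0 0 0.150000712 64
66 5 130 0 0 0.298125918 65
67 2 132 0 0 0.150000428 66
68 2 134 0 0 0.15 67
69 2 136 0 0 0.15 68
70 2 138 0 0 0.15 69
71 2 140 0 0 0.15 70
72 2 142 0 0 0.15 71
73 2 144 0 0 0.15 72
74 2 146 0 0 0.15 73
75 2 148 0 0 0.15 74
76 2 150 0 0 0.15 75
77 2 152 0 0 0.15 76
78 2 154 0 0 0.150000059 77
79 5 156 0 0 0.398121226 78
80 2 158 0 0 0.1500146 79
81 2 160 0 0 0.15 80
82 2 162 0 0 0.15 81
83 2 164 0 0 0.15 82
84 2 166 0 0 0.15 83
85 2 168 0 0 0.15 84
86 2 170 0 0 0.15 85
87 2 172 0 0 0.15 86
88 2 174 0 0 0.15 87
89 2 176 0 0 0.15 88
90 2 178 0 0 0.151427959 89
91 2 180 0 0 0.212809199 90
92 2 182 0 0 0.15 91
93 2 184 0 0 0.15 92
94 2 186 0 0 0.15 93
95 2 188 0 0 0.15 94
96 2 190 0 0 0.15 95
97 2 192 0 0 0.15 96
98 2 194 0 0 0.15 97
99 2 196 0 0 0.15 98
100 2 198 0 0 0.15 99
101 2 200 0 0 0.189461064 100
102 2 202 0 0 0.152554963 101
103 2 204 0 0 0.15 102
104 2 206 0 0 0.15 103
105 2 208 0 0 0.15 104
106 2 210 0 0 0.15 105
107 2 212 0 0 0.15 106
108 2 214 0 0 0.15 107
109 2 216 0 0 0.15 108
110 2 218 0 0 0.15 109
111 2 220 0 0 0.15 110
112 2 222 0 0 0.150419729 111
113 5 224 0 0 0.328610357 112
114 2 226 0 0 0.150000001 113
115 2 228 0 0 0.15 114
116 2 230 0 0 0.15 115
117 2 232 0 0 0.15 116
118 2 234 0 0 0.15 117
119 2 236 0 0 0.15 118
120 2 238 0 0 0.15 119
121 2 240 0 0 0.15 120
122 2 242 0 0 0.150071356 121
123 5 244 0 0 0.258058019 122
124 2 246 0 0 0.150000002 123
125 2 248 0 0 0.15 124
126 2 250 0 0 0.15 125
127 2 252 0 0 0.15 126
128 2 254 0 0 0.15 127
129 2 256 0 0 0.15 128
130 2 258 0 0 0.15 129
131 2 260 0 0 0.15 130
132 2 262 0 0 0.15 131
133 2 264 0 0 0.15 132
134 2 266 0 0 0.157711307 133
135 2 268 0 0 0.196247213 134
136 2 270 0 0 0.15 135
137 2 272 0 0 0.15 136
138 2 274 0 0 0.15 137
139 2 276 0 0 0.15 138
140 2 278 0 0 0.15 139
141 2 280 0 0 0.15 140
142 2 282 0 0 0.15 141
143 2 284 0 0 0.15 142
144 2 286 0 0 0.15 143
145 2 288 0 0 0.150002832 144
146 5 290 0 0 0.278108111 145
147 2 292 0 0 0.15000008 146
148 2 294 0 0 0.15 147
149 2 296 0 0 0.15 148
150 2 298 0 0 0.15 149
151 2 300 0 0 0.15 150
152 2 302 0 0 0.15 151
153 2 304 0 0 0.15 152
154 2 306 0 0 0.15 153
155 2 308 0 0 0.15 154
156 2 310 0 0 0.15 155
157 2 312 0 0 0.15 156
158 2 314 0 0 0.153506065 157
159 2 316 0 0 0.189681359 158
160 2 318 0 0 0.15 159
161 2 320 0 0 0.15 160
162 2 322 0 0 0.15 161
163 2 324 0 0 0.15 162
164 2 326 0 0 0.15 163
165 2 328 0 0 0.15 164
166 2 330 0 0 0.15 165
167 2 332 0 0 0.15 166
168 2 334 0 0 0.15 167
169 5 336 0 0 0.304709608 168
170 2 338 0 0 0.150811155 169
171 2 340 0 0 0.15 170
172 2 342 0 0 0.15 171
173 2 344 0 0 0.15 172
174 2 346 0 0 0.15 173
175 2 348 0 0 0.15 174
176 2 350 0 0 0.15 175
177 2 352 0 0 0.15 176
178 2 354 0 0 0.15 177
179 2 356 0 0 0.15 178
180 2 358 0 0 0.15 179
181 2 360 0 0 0.151776034 180
182 5 362 0 0 0.236281216 181
183 2 364 0 0 0.15 182
184 2 366 0 0 0.15 183
185 2 368 0 0 0.15 184
186 2 370 0 0 0.15 185
187 2 372 0 0 0.15 186
188 2 374 0 0 0.15 187
189 2 376 0 0 0.15 188
190 2 378 0 0 0.15 189
191 2 380 0 0 0.15 190
192 2 382 0 0 0.15 191
193 2 384 0 0 0.15 192
194 2 386 0 0 0.15 193
195 2 388 0 0 0.15 194
196 2 390 0 0 0.15 195
197 2 392 0 0 0.15 196
198 2 394 0 0 0.15 197
199 2 396 0 0 0.15 198
200 2 398 0 0 0.15 199
201 2 400 0 0 0.15 200
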