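t_days,dose_Gy
0,2
1,2
2,2
3,2
4,2
7,2
8,2
9,2
10,2
11,2
14,2
15,2
16,2
17,2
18,2
21,2
22,2
23,2
24,2
25,2
28,2
29,2
30,2
31,2
32,2
35,2
36,2
37,2
38,2
39,2
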