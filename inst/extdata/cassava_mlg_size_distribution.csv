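size,snp_n,silico_n
1,1567,1568
2,472,495
3,191,174
4,96,101
5,61,56
6,31,32
7,21,21
8,14,14
9,15,14
10,8,9
11,8,9
12,6,7
13,7,3
14,2,4
15,1,3
16,3,2
17,1,0
18,1,1
19,1,0
20,1,2
21,1,1
24,1,0
25,0,1
29,1,0
30,1,2
31,1,0
32,0,1
39,1,0
40,0,1
42,0,1
43,2,1
46,0,1
47,1,0
62,1,1
84,1,0
87,0,1
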