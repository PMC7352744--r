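run,A,B,C,D,E
1,4,2,1,1.5,91.5
2,4,3,1,3,89
3,4,3,2,3,88
4,5,2.5,1.5,2.25,88.75
5,6,2,1,3,88
6,6,2,1.5,1.5,89
7,6,2.5,2,1.5,88
8,4,2,2,1.5,90.5
9,6,3,1,1.5,88.5
10,6,3,1.5,3,86.5
11,5,3,2,1.5,88.5
12,6,3,2,2.25,86.75
13,6,2,2,3,87
14,4,2,1.5,3,89.5
15,4,3,1.5,1.5,90
16,5,2,1,1.5,90.5
17,5,3,1,3,88
18,5,2,2,3,88
19,5,3,1,1.5,89.5
20,5,2,2,1.5,89.5
21,5,2.5,1.5,2.25,88.75
22,5,2.5,1.5,2.25,88.75
23,5,2.5,1.5,2.25,88.75
24,4,3,2,3,88
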