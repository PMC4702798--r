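index,region,master_column
1,I,1
2,I,2
3,I,3
4,g.l,4
5,g.l,5
6,g.l,6
7,g.l,7
8,g.l,8
9,g.l,9
10,II,10
11,II,11
12,II,12
13,II,13
14,III,14
15,III,15
16,III,16
17,III,17
18,III,18
19,III,19
20,aC,20
21,aC,21
22,aC,22
23,aC,23
24,aC,24
25,aC,25
26,aC,26
27,aC,27
28,aC,28
29,aC,29
30,aC,30
31,b.l,31
32,b.l,32
33,b.l,33
34,b.l,34
35,b.l,35
36,b.l,36
37,b.l,37
38,IV,38
39,IV,39
40,IV,40
41,IV,41
42,V,42
43,V,43
44,V,44
45,GK,45
46,hinge,46
47,hinge,47
48,hinge,48
49,linker,49
50,linker,50
51,linker,51
52,linker,52
53,aD,53
54,aD,54
55,aD,55
56,aD,56
57,aD,57
58,aD,58
59,aD,59
60,aE,60
61,aE,61
62,aE,62
63,aE,63
64,aE,64
65,VI,65
66,VI,66
67,VI,67
68,c.l,68
69,c.l,69
70,c.l,70
71,c.l,71
72,c.l,72
73,c.l,73
74,c.l,74
75,c.l,75
76,VII,76
77,VII,77
78,VII,78
79,VIII,79
80,xDFG,80
81,xDFG,81
82,xDFG,82
83,a.l,83
84,a.l,84
85,a.l,85
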