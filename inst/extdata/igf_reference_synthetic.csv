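age,sex,mu,sigma
18,male,5.58468163101553,0.25
19,male,5.57268163101553,0.25
20,male,5.56068163101553,0.25
21,male,5.54868163101553,0.25
22,male,5.53668163101553,0.25
23,male,5.52468163101553,0.25
24,male,5.51268163101553,0.25
25,male,5.50068163101553,0.25
26,male,5.48868163101553,0.25
27,male,5.47668163101553,0.25
28,male,5.46468163101553,0.25
29,male,5.45268163101553,0.25
30,male,5.44068163101553,0.25
31,male,5.42868163101553,0.25
32,male,5.41668163101553,0.25
33,male,5.40468163101553,0.25
34,male,5.39268163101553,0.25
35,male,5.38068163101553,0.25
36,male,5.36868163101553,0.25
37,male,5.35668163101553,0.25
38,male,5.34468163101553,0.25
39,male,5.33268163101553,0.25
40,male,5.32068163101553,0.25
41,male,5.30868163101553,0.25
42,male,5.29668163101553,0.25
43,male,5.28468163101553,0.25
44,male,5.27268163101553,0.25
45,male,5.26068163101553,0.25
46,male,5.24868163101553,0.25
47,male,5.23668163101553,0.25
48,male,5.22468163101553,0.25
49,male,5.21268163101553,0.25
50,male,5.20068163101553,0.25
51,male,5.18868163101553,0.25
52,male,5.17668163101553,0.25
53,male,5.16468163101553,0.25
54,male,5.15268163101553,0.25
55,male,5.14068163101553,0.25
56,male,5.12868163101553,0.25
57,male,5.11668163101553,0.25
58,male,5.10468163101553,0.25
59,male,5.09268163101553,0.25
60,male,5.08068163101553,0.25
61,male,5.06868163101553,0.25
62,male,5.05668163101553,0.25
63,male,5.04468163101553,0.25
64,male,5.03268163101553,0.25
65,male,5.02068163101553,0.25
66,male,5.00868163101553,0.25
67,male,4.99668163101553,0.25
68,male,4.98468163101553,0.25
69,male,4.97268163101553,0.25
70,male,4.96068163101553,0.25
71,male,4.94868163101553,0.25
72,male,4.93668163101553,0.25
73,male,4.92468163101553,0.25
74,male,4.91268163101553,0.25
75,male,4.90068163101553,0.25
76,male,4.88868163101553,0.25
77,male,4.87668163101553,0.25
78,male,4.86468163101553,0.25
79,male,4.85268163101553,0.25
80,male,4.84068163101553,0.25
18,female,5.53338833662798,0.25
19,female,5.52138833662798,0.25
20,female,5.50938833662798,0.25
21,female,5.49738833662798,0.25
22,female,5.48538833662798,0.25
23,female,5.47338833662798,0.25
24,female,5.46138833662798,0.25
25,female,5.44938833662798,0.25
26,female,5.43738833662798,0.25
27,female,5.42538833662798,0.25
28,female,5.41338833662798,0.25
29,female,5.40138833662798,0.25
30,female,5.38938833662798,0.25
31,female,5.37738833662798,0.25
32,female,5.36538833662798,0.25
33,female,5.35338833662798,0.25
34,female,5.34138833662798,0.25
35,female,5.32938833662798,0.25
36,female,5.31738833662798,0.25
37,female,5.30538833662798,0.25
38,female,5.29338833662798,0.25
39,female,5.28138833662798,0.25
40,female,5.26938833662798,0.25
41,female,5.25738833662798,0.25
42,female,5.24538833662798,0.25
43,female,5.23338833662798,0.25
44,female,5.22138833662798,0.25
45,female,5.20938833662798,0.25
46,female,5.19738833662798,0.25
47,female,5.18538833662798,0.25
48,female,5.17338833662798,0.25
49,female,5.16138833662798,0.25
50,female,5.14938833662798,0.25
51,female,5.13738833662798,0.25
52,female,5.12538833662798,0.25
53,female,5.11338833662798,0.25
54,female,5.10138833662798,0.25
55,female,5.08938833662798,0.25
56,female,5.07738833662798,0.25
57,female,5.06538833662798,0.25
58,female,5.05338833662798,0.25
59,female,5.04138833662798,0.25
60,female,5.02938833662798,0.25
61,female,5.01738833662798,0.25
62,female,5.00538833662798,0.25
63,female,4.99338833662798,0.25
64,female,4.98138833662798,0.25
65,female,4.96938833662798,0.25
66,female,4.95738833662798,0.25
67,female,4.94538833662798,0.25
68,female,4.93338833662798,0.25
69,female,4.92138833662798,0.25
70,female,4.90938833662798,0.25
71,female,4.89738833662798,0.25
72,female,4.88538833662798,0.25
73,female,4.87338833662798,0.25
74,female,4.86138833662798,0.25
75,female,4.84938833662798,0.25
76,female,4.83738833662798,0.25
77,female,4.82538833662798,0.25
78,female,4.81338833662798,0.25
79,female,4.80138833662798,0.25
80,female,4.78938833662798,0.25
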