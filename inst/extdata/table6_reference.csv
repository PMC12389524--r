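compound,measured_ic50_nM,measured,hm,rf,gep,gbdt,poly_svm,mix_svm,is_test
1,177,2.25,2.39,2.31,2.05,2.06,2.31,2.26,TRUE
2,180,2.26,2.39,2.33,2.13,2.06,2.28,2.34,TRUE
3,378,2.58,2.43,2.39,2.16,2.06,2.18,2.32,FALSE
4,217,2.34,2.40,2.38,2.11,1.94,2.36,2.35,FALSE
5,242,2.38,2.37,2.39,2.08,1.92,2.42,2.37,TRUE
6,572,2.76,2.44,2.38,2.15,2.16,2.45,2.75,FALSE
7,31,1.49,1.32,1.43,1.14,1.34,1.26,1.33,TRUE
8,22,1.34,1.17,1.42,1.40,1.41,1.27,1.35,FALSE
9,29,1.46,1.34,1.34,1.20,1.45,1.38,1.45,FALSE
10,27,1.43,1.42,1.50,1.27,1.45,1.42,1.44,FALSE
11,11,1.04,1.38,1.23,1.50,1.21,1.46,1.05,FALSE
12,37,1.57,1.34,1.34,1.26,1.51,1.23,1.56,FALSE
13,18,1.26,1.87,1.47,1.13,1.35,1.38,1.27,FALSE
14,448,2.65,2.27,2.50,2.24,2.07,2.31,2.64,FALSE
15,249,2.40,2.26,2.50,2.36,1.99,2.34,2.29,TRUE
16,206,2.31,2.43,2.38,2.09,1.98,2.18,2.32,FALSE
17,256,2.41,2.36,2.47,2.05,1.99,2.81,2.42,FALSE
18,158,2.20,2.35,2.39,2.20,1.89,2.57,2.21,FALSE
19,341,2.53,2.26,2.50,2.27,2.01,2.75,2.57,TRUE
20,261,2.42,2.95,2.41,2.18,2.00,2.27,2.41,TRUE
21,42,1.62,1.38,1.47,1.43,1.55,1.36,1.23,FALSE
22,19,1.28,1.23,1.18,1.37,1.36,1.44,1.29,FALSE
23,23,1.36,1.38,1.27,1.20,1.40,1.39,1.40,FALSE
24,21,1.32,1.20,1.29,1.21,1.39,1.53,1.31,FALSE
25,13,1.11,1.17,1.18,1.10,1.26,1.47,1.12,FALSE
26,60,1.78,1.25,1.73,1.21,1.67,1.60,1.44,TRUE
27,26,1.41,1.74,1.45,1.02,1.41,1.33,1.42,FALSE
28,375,2.57,2.30,2.20,2.36,2.46,2.22,2.22,TRUE
29,1571,3.20,2.84,2.54,2.26,2.42,3.05,3.19,FALSE
30,170,2.23,2.29,2.23,2.47,1.89,2.42,2.22,FALSE
31,1963,3.29,2.83,2.42,2.44,2.47,2.93,3.28,FALSE
32,7.6,0.88,1.22,0.73,1.08,1.10,0.62,0.87,FALSE
33,56,1.75,1.74,1.81,1.30,1.63,1.36,1.76,FALSE
34,175,2.24,1.77,1.84,1.42,1.81,1.44,1.89,FALSE
35,11,1.04,1.32,0.91,1.17,1.24,0.93,0.62,FALSE
36,24,1.38,1.28,1.40,1.21,1.41,1.11,1.37,FALSE
37,38,1.58,1.35,1.15,1.08,1.50,1.23,1.57,FALSE
38,71,1.85,2.28,1.90,1.30,1.67,2.32,1.86,FALSE
39,204,2.31,2.29,2.03,1.42,1.93,2.45,2.30,FALSE
40,4.6,0.66,1.27,0.92,1.17,1.10,1.00,0.67,FALSE
41,100,2.00,1.80,2.08,1.21,1.76,2.33,2.01,FALSE
42,1.9,0.28,0.42,0.57,1.08,0.82,0.51,0.29,FALSE
43,2.8,0.45,0.51,0.87,2.44,0.87,0.91,0.71,FALSE
44,92,1.96,2.28,1.87,2.11,1.76,1.63,1.97,FALSE
45,14,1.15,0.64,1.08,1.22,1.07,1.50,1.15,TRUE
46,100,2.00,1.71,1.74,0.83,1.76,2.33,1.99,FALSE
47,30,1.48,1.57,1.78,2.40,1.49,1.76,1.53,FALSE
48,17,1.23,1.83,1.65,0.66,1.36,1.56,1.48,FALSE
49,86,1.93,1.83,1.77,0.89,1.72,1.76,1.92,FALSE
50,289,2.46,1.86,2.18,2.17,2.01,2.12,2.45,FALSE
51,90,1.95,1.86,1.78,2.33,1.71,1.60,1.52,FALSE
52,63,1.80,1.83,1.88,1.96,1.68,1.91,1.81,FALSE
53,127,2.10,1.83,1.94,2.10,1.81,1.95,2.09,FALSE
54,28,1.45,2.34,1.65,2.10,1.43,1.84,1.46,FALSE
55,2.1,0.32,1.00,0.99,2.27,1.08,0.66,0.33,FALSE
56,19,1.28,1.02,1.07,2.07,1.16,0.97,1.27,FALSE
57,11,1.04,1.34,1.04,1.89,1.29,0.87,1.05,FALSE
58,20,1.30,1.44,1.08,2.31,1.29,0.97,1.29,FALSE
59,26,1.41,1.70,1.39,1.92,1.32,0.99,1.40,FALSE
60,3.2,0.51,0.93,0.79,1.06,1.03,0.73,0.52,FALSE
61,2.5,0.40,0.46,0.48,1.10,0.88,0.49,0.39,FALSE
62,0.9,-0.05,0.52,0.47,1.08,0.74,0.34,0.18,FALSE
63,3.4,0.53,0.55,0.42,1.00,0.95,0.27,0.52,FALSE
64,4.3,0.63,0.61,0.54,0.98,0.99,0.45,0.64,FALSE
65,15,1.18,1.04,0.90,0.83,1.00,1.17,0.84,TRUE
66,20,1.30,1.05,1.11,1.02,1.39,0.97,1.29,FALSE
67,4.1,0.61,0.62,0.55,0.94,1.08,0.56,0.41,TRUE
68,6.3,0.80,1.09,0.67,0.49,1.06,1.03,0.81,FALSE
69,1.8,0.26,0.44,0.40,0.76,1.11,0.12,0.44,TRUE
70,2.2,0.34,0.53,0.41,0.90,0.99,0.36,0.53,TRUE
71,3.7,0.57,0.58,0.57,0.61,0.97,0.53,0.48,FALSE
72,2.1,0.32,0.50,0.41,0.53,0.88,0.01,0.33,FALSE
73,3.6,0.56,0.53,0.41,0.67,0.99,0.20,0.51,FALSE
74,2.5,0.40,0.55,0.59,0.97,1.02,0.74,0.67,TRUE
75,10,1.00,1.27,1.20,0.67,1.19,1.47,1.01,FALSE
76,3.7,0.57,0.40,0.40,1.19,1.00,0.19,0.46,TRUE
77,8.5,0.93,0.48,0.70,1.65,1.33,0.93,0.75,TRUE
78,4.1,0.61,0.39,0.57,0.73,1.00,0.65,0.62,FALSE
79,70.1,1.85,1.13,1.36,1.24,1.67,1.62,1.84,FALSE
80,5.1,0.71,1.39,1.23,0.52,1.03,1.39,1.28,FALSE
81,34,1.53,1.46,1.60,0.97,1.50,1.47,1.52,FALSE
82,71,1.85,1.93,1.68,0.53,0.85,1.52,1.85,TRUE
83,7.9,0.90,1.33,1.16,0.78,1.07,1.36,1.21,FALSE
84,18,1.26,1.37,1.19,1.12,1.35,1.37,1.27,FALSE
85,26,1.41,1.41,1.54,1.16,1.43,1.41,1.42,FALSE
86,49,1.69,1.44,1.48,1.42,1.59,1.42,1.44,FALSE
87,15,1.18,1.39,1.53,0.95,1.31,1.38,1.21,FALSE
88,36,1.56,1.41,1.54,1.02,1.25,1.52,1.53,TRUE
89,71,1.85,1.43,1.72,1.95,1.67,1.65,1.84,FALSE
90,58,1.76,1.32,1.56,1.72,1.62,1.39,1.37,FALSE
91,71,1.85,1.38,1.73,1.52,1.67,1.73,1.84,FALSE
92,77,1.89,1.31,1.58,1.82,1.70,1.38,1.21,FALSE
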