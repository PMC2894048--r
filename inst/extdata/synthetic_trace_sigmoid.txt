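# synthetic thioflavin-T style aggregation trace (sigmoid forward model)
# time_h  signal_au
0	0.0222339
1.15625	0.0147424
2.3125	0.0293334
3.46875	0.0270232
4.625	0.0390335
5.78125	0.0336167
6.9375	0.0239691
8.09375	0.0591145
9.25	0.136721
10.4062	0.251803
11.5625	0.430781
12.7188	0.647275
13.875	0.825054
15.0312	0.919888
16.1875	0.967126
17.3438	0.988244
18.5	1.00627
19.6562	0.997419
20.8125	0.998147
21.9688	0.996829
23.125	1.01527
24.2812	1.0016
25.4375	1.01306
26.5938	1.01287
27.75	1.00593
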