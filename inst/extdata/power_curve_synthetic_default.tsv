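# covpower power curve; fit_mode=isotonic clamp_hi=226 domain_lo=0
# s power
0 0
1 0
2 0.158416
3 0.158416
4 0.493333
5 0.538462
6 0.68
7 0.68
8 0.847826
9 0.847826
10 0.96
11 1
12 1
13 1
14 1
15 1
16 1
17 1
18 1
19 1
20 1
22 1
23 1
24 1
25 1
26 1
27 1
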