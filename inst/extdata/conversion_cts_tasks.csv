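# {"condition":"cts","subscale":"tasks","provenance":"published","n_items":6}
raw_score,theta_eap,rasch_score
6,NA,0
7,NA,9
8,NA,16
9,NA,21
10,NA,26
11,NA,30
12,NA,34
13,NA,37
14,NA,41
15,NA,44
16,NA,47
17,NA,50
18,NA,53
19,NA,56
20,NA,59
21,NA,62
22,NA,65
23,NA,68
24,NA,72
25,NA,75
26,NA,79
27,NA,83
28,NA,88
29,NA,93
30,NA,100
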