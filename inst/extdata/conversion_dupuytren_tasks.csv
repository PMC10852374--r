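# {"condition":"dupuytren","subscale":"tasks","provenance":"published","n_items":6}
raw_score,theta_eap,rasch_score
6,NA,0
7,NA,19
8,NA,30
9,NA,37
10,NA,43
11,NA,49
12,NA,53
13,NA,57
14,NA,61
15,NA,65
16,NA,69
17,NA,72
18,NA,76
19,NA,80
20,NA,84
21,NA,89
22,NA,93
23,NA,97
24,NA,100
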