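# {"condition":"dupuytren","subscale":"symptoms","provenance":"published","n_items":3}
raw_score,theta_eap,rasch_score
3,NA,0
4,NA,27
5,NA,43
6,NA,54
7,NA,63
8,NA,71
9,NA,79
10,NA,88
11,NA,95
12,NA,100
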