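# {"condition":"cts","subscale":"symptoms","provenance":"published","n_items":3}
raw_score,theta_eap,rasch_score
3,NA,0
4,NA,15
5,NA,27
6,NA,38
7,NA,48
8,NA,59
9,NA,71
10,NA,85
11,NA,100
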