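patient_id,time_days,event
1,50,graft_failure
2,131,graft_failure
3,90,death
4,365,censored
5,400,censored
6,450,censored
7,500,censored
8,550,censored
9,600,censored
10,650,censored
11,700,censored
12,730,censored
13,760,censored
14,800,censored
15,850,censored
16,900,censored
17,1460,censored
18,2920,censored
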