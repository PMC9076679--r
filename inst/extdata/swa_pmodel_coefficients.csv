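block,term,estimate,se
A,(Intercept),8.94,0.02
a,(Intercept),-0.02,0.02
A,DEPTH,0.06,0.02
a,DEPTH,-0.17,0.02
A,SST,0.37,0.02
a,SST,0.06,0.03
A,CURL,0.15,0.01
a,CURL,-0.05,0.02
A,SSTA,-0.13,0.01
a,SSTA,0.09,0.02
A,ICE08,-0.08,0.03
a,ICE08,-0.39,0.04
B,(Intercept),-0.60,0.03
b,(Intercept),-0.12,0.05
B,DEPTH,-0.01,0.03
b,DEPTH,0.18,0.04
B,SST,-0.68,0.03
b,SST,0.11,0.05
B,CURL,-0.17,0.03
b,CURL,-0.23,0.04
B,SSTA,0.13,0.02
b,SSTA,-0.11,0.03
B,ICE08,0.47,0.08
b,ICE08,2.17,0.15
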