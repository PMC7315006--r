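animal,trial,attempt,success,duration_s,pre_strike
A,1,TRUE,TRUE,2.6,TRUE
B,1,TRUE,TRUE,5.7,TRUE
C,1,TRUE,TRUE,3.9,TRUE
D,1,TRUE,TRUE,34.7,FALSE
D,1,TRUE,TRUE,7.3,TRUE
D,2,TRUE,TRUE,13.7,TRUE
D,3,TRUE,TRUE,5.3,TRUE
D,4,TRUE,TRUE,24.3,FALSE
D,4,TRUE,TRUE,35.3,FALSE
D,4,TRUE,TRUE,12.5,FALSE
D,4,TRUE,TRUE,33.0,TRUE
E,1,TRUE,TRUE,8.5,FALSE
E,1,TRUE,TRUE,3.6,TRUE
F,1,TRUE,FALSE,24.8,TRUE
F,1,TRUE,FALSE,12.9,FALSE
G,1,TRUE,FALSE,17.7,TRUE
G,1,TRUE,FALSE,23.3,FALSE
G,2,FALSE,FALSE,18.2,FALSE
G,2,FALSE,FALSE,42.0,FALSE
G,2,FALSE,FALSE,12.5,FALSE
G,3,FALSE,FALSE,19.0,FALSE
H,1,FALSE,FALSE,12.1,FALSE
H,1,FALSE,FALSE,6.7,FALSE
H,1,FALSE,FALSE,5.1,FALSE
H,2,FALSE,FALSE,31.7,FALSE
H,2,FALSE,FALSE,13.8,FALSE
I,1,FALSE,FALSE,6.9,FALSE
J,1,FALSE,FALSE,11.6,FALSE
J,1,FALSE,FALSE,5.7,FALSE
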