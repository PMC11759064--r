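code,lambda,sigma,mass
G,0.45,4.5,57.05
S,0.46,5.2,87.08
A,0.60,5.0,71.08
L,0.97,6.2,113.16
F,1.00,6.4,147.18
K,0.39,6.4,128.17
Q,0.56,6.0,128.13
P,0.67,5.6,97.12
Y,0.95,6.5,163.18
R,0.60,6.6,156.19
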