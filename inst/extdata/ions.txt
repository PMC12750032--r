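# Monoatomic and simple metal/halide ions
NA
K
LI
RB
CS
MG
CA
SR
BA
MN
FE
FE2
CO
NI
CU
CU1
ZN
CD
HG
PB
AL
CL
BR
IOD
F
OH
PT
AU
AG
W
YB
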