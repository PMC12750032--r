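# Common enzymatic cofactors and prosthetic groups
NAD
NAI
NAP
NDP
FAD
FMN
ATP
ADP
AMP
ANP
GTP
GDP
GNP
COA
ACO
SAM
SAH
PLP
TPP
TDP
HEM
HEC
HEA
B12
BTN
THF
FFO
MQN
UQ1
PQQ
F43
SF4
FES
H4B
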