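component_id	count
ATP	6000
ADP	4500
NAD	2200
HEM	5100
GOL	14000
EDO	11000
SO4	20000
ZN	12000
MG	18000
STI	120
LVY	8
QQ2	3
BEN	350
IRE	45
07J	12
ASP	900
GLC	3200
MYR	600
CLR	250
PLM	700
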