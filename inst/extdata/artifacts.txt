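# Buffer molecules, cryoprotectants and precipitants from crystallization
GOL
EDO
PEG
PG4
P6G
1PE
MPD
DMS
ACT
FMT
ACY
BME
MRD
TRS
EPE
MES
IMD
PO4
SO4
NO3
CIT
FLC
TLA
TAR
MLI
OXL
CAC
NH4
AZI
SCN
BCT
CO3
PGE
DIO
BU3
PDO
EOH
IPA
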