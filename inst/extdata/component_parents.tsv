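component_id	parent	one_letter	class
ALA	ALA	A	amino
ARG	ARG	R	amino
ASN	ASN	N	amino
ASP	ASP	D	amino
CYS	CYS	C	amino
GLN	GLN	Q	amino
GLU	GLU	E	amino
GLY	GLY	G	amino
HIS	HIS	H	amino
ILE	ILE	I	amino
LEU	LEU	L	amino
LYS	LYS	K	amino
MET	MET	M	amino
PHE	PHE	F	amino
PRO	PRO	P	amino
SER	SER	S	amino
THR	THR	T	amino
TRP	TRP	W	amino
TYR	TYR	Y	amino
VAL	VAL	V	amino
MSE	MET	M	amino
SEP	SER	S	amino
TPO	THR	T	amino
PTR	TYR	Y	amino
MLY	LYS	K	amino
M3L	LYS	K	amino
KCX	LYS	K	amino
CSO	CYS	C	amino
CME	CYS	C	amino
CSD	CYS	C	amino
OCS	CYS	C	amino
HYP	PRO	P	amino
FME	MET	M	amino
PCA	GLU	E	amino
ALY	LYS	K	amino
MLZ	LYS	K	amino
HIC	HIS	H	amino
NEP	HIS	H	amino
DA	DA	A	nucleic-dna
DC	DC	C	nucleic-dna
DG	DG	G	nucleic-dna
DT	DT	T	nucleic-dna
DI	DG	G	nucleic-dna
5CM	DC	C	nucleic-dna
6MA	DA	A	nucleic-dna
8OG	DG	G	nucleic-dna
A	A	A	nucleic-rna
C	C	C	nucleic-rna
G	G	G	nucleic-rna
U	U	U	nucleic-rna
PSU	U	U	nucleic-rna
5MC	C	C	nucleic-rna
5MU	U	U	nucleic-rna
1MA	A	A	nucleic-rna
7MG	G	G	nucleic-rna
OMC	C	C	nucleic-rna
OMG	G	G	nucleic-rna
OMU	U	U	nucleic-rna
I	G	G	nucleic-rna
UNK	UNK	X	unknown
UNX	UNX	X	unknown
N	N	X	unknown
DN	DN	X	unknown
ASX	ASX	B	unknown
GLX	GLX	Z	unknown
ACE	ACE	X	non-linking
NH2	NH2	X	non-linking
NME	NME	X	non-linking
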