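codon	amino_acid	preferred
TTT	F	0
TTC	F	1
TTA	L	0
TTG	L	0
TCT	S	0
TCC	S	1
TCA	S	0
TCG	S	0
TAT	Y	0
TAC	Y	1
TGT	C	0
TGC	C	1
TGG	W	1
CTT	L	0
CTC	L	0
CTA	L	0
CTG	L	1
CCT	P	0
CCC	P	1
CCA	P	0
CCG	P	0
CAT	H	0
CAC	H	1
CAA	Q	0
CAG	Q	1
CGT	R	0
CGC	R	1
CGA	R	0
CGG	R	0
ATT	I	0
ATC	I	1
ATA	I	0
ATG	M	1
ACT	T	0
ACC	T	1
ACA	T	0
ACG	T	0
AAT	N	0
AAC	N	1
AAA	K	0
AAG	K	1
AGT	S	0
AGC	S	0
AGA	R	0
AGG	R	0
GTT	V	0
GTC	V	0
GTA	V	0
GTG	V	1
GCT	A	0
GCC	A	1
GCA	A	0
GCG	A	0
GAT	D	0
GAC	D	1
GAA	E	0
GAG	E	1
GGT	G	0
GGC	G	1
GGA	G	0
GGG	G	0
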