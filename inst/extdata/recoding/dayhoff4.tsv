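# Dayhoff-group collapse to four states: the three conservative Dayhoff
# groups (AGPST, DENQ, HKR) are kept and the remaining residues
# (C, FWY, ILMV) are merged, written as nucleotide characters.
residue	code
A	A
G	A
P	A
S	A
T	A
D	C
E	C
N	C
Q	C
H	G
K	G
R	G
C	T
F	T
I	T
L	T
M	T
V	T
W	T
Y	T
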