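# Amino-acid residue composition (residue = free amino acid minus one water)
# and mean residue volumes in cubic Angstrom (Zamyatnin-style partial volumes
# widely used for protein partial specific volume and density estimates).
code1	code3	formula	volume
A	ALA	C3H5NO	88.6
R	ARG	C6H12N4O	173.4
N	ASN	C4H6N2O2	114.1
D	ASP	C4H5NO3	111.1
C	CYS	C3H5NOS	108.5
Q	GLN	C5H8N2O2	143.8
E	GLU	C5H7NO3	138.4
G	GLY	C2H3NO	60.1
H	HIS	C6H7N3O	153.2
I	ILE	C6H11NO	166.7
L	LEU	C6H11NO	166.7
K	LYS	C6H12N2O	168.6
M	MET	C5H9NOS	162.9
F	PHE	C9H9NO	189.9
P	PRO	C5H7NO	112.7
S	SER	C3H5NO2	89.0
T	THR	C4H7NO2	116.1
W	TRP	C11H10N2O	227.8
V	VAL	C5H9NO	140.0
Y	TYR	C9H9NO2	193.6
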