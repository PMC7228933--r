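# Element symbols and atomic numbers (electron counts of the neutral atom).
symbol	z
H	1
He	2
Li	3
Be	4
B	5
C	6
N	7
O	8
F	9
Ne	10
Na	11
Mg	12
Al	13
Si	14
P	15
S	16
Cl	17
Ar	18
K	19
Ca	20
Mn	25
Fe	26
Co	27
Ni	28
Cu	29
Zn	30
Se	34
Br	35
Mo	42
I	53
W	74
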