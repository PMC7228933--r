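# Displaced-solvent volumes per heavy-atom element (cubic Angstrom),
# standard values used for excluded-volume dummy-solvent corrections.
element	volume
H	5.15
C	16.44
N	2.49
O	9.13
S	19.86
P	5.73
Fe	7.99
Zn	9.85
Ca	31.89
Mg	16.79
Mn	9.20
Cu	8.78
Se	28.73
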