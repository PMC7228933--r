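# Head-group volumes (cubic Angstrom) for common solubilization detergents,
# keyed by the head-group chemical formula. Values are literature consensus
# head volumes used in detergent-micelle and corona modeling.
name	formula	volume
maltoside	C12H21O11	350
glucoside	C6H11O6	190
LDAO	C2H6NO	77
phosphocholine	C5H13NO4P	218
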