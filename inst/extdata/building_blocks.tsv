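code	name	formula	rt_window	dH	dN	dF	dS
Hex	hexose	C6H10O5	30	1	0	0	0
HexNAc	N-acetylhexosamine	C8H13NO5	30	0	1	0	0
HexHexNAc	hexose + N-acetylhexosamine	C14H23NO10	30	1	1	0	0
Fuc	deoxyhexose (fucose)	C6H10O4	20	0	0	1	0
NeuAc	N-acetylneuraminic acid	C11H17NO8	120	0	0	0	1
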