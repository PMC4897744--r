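gene5	gene3
BCR	ABL1
ETV6	RUNX1
TCF3	PBX1
TCF3	HLF
P2RY8	CRLF2
IGH	CRLF2
IGH	CEBPE
IGH	DUX4
ERG	DUX4
EP300	ZNF384
TAF15	ZNF384
TCF3	ZNF384
PAX5	ZNF521
PAX5	JAK2
PAX5	ESRRB
PAX5	FOXP1
PAX5	DACH1
PAX5	ETV6
MEF2D	HNRNPUL1
IKZF1	NUTM1
NONO	TFE3
ZCCHC7	PAX5
MLL	AFF1
MLL	GAS7
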