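name	motif
EcoRV	GATATC
ApaLI	GTGCAC
BamHI	GGATCC
HindIII	AAGCTT
NotI	GCGGCCGC
SwaI	ATTTAAAT
PacI	TTAATTAA
AscI	GGCGCGCC
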