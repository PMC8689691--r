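name	recognition	cut_offset_top	cut_offset_bottom
BsaI	GGTCTC	1	5
BsmBI	CGTCTC	1	5
NotI	GCGGCCGC	-6	-2
EcoRI	GAATTC	-5	-1
XbaI	TCTAGA	-5	-1
SpeI	ACTAGT	-5	-1
PstI	CTGCAG	-1	-5
BglII	AGATCT	-5	-1
BamHI	GGATCC	-5	-1
XhoI	CTCGAG	-5	-1
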