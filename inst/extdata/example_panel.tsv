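gene	intolerance	pubweight
NOD2	-1.28	245
IL23R	0.33	118
ATG16L1	-0.45	156
IRGM	0.91	62
LRRK2	-1.02	89
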