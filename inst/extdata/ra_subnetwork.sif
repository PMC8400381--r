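TNF	ACTIVATION	IL6
NFKB1	ACTIVATION	IL6
IL6	ACTIVATION	IL6
IL6	ACTIVATION	TGFB1
TGFB1	ACTIVATION	TGFB1
IL6	ACTIVATION	ILK
ILK	ACTIVATION	MAP2K1
MAP2K1	ACTIVATION	MAPK1
MAP2K1	ACTIVATION	MAPK14
TGFB1	ACTIVATION	MAPK14
TNF	ACTIVATION	MAPK14
TGFB1	ACTIVATION	DAXX
IL6	ACTIVATION	NFKB1
TNF	ACTIVATION	NFKB1
MAPK14	ACTIVATION	NFKB1
DAXX	ACTIVATION	NFKB1
NFKB1	ACTIVATION	NFKBIA
ILK	ACTIVATION	NFKBIA
MAPK14	ACTIVATION	NFKBIA
MAPK14	ACTIVATION	JUN
ILK	ACTIVATION	JUN
TGFB1	ACTIVATION	JUN
MAPK14	ACTIVATION	FOS
ILK	ACTIVATION	FOS
TGFB1	ACTIVATION	FOS
MAPK14	ACTIVATION	JUND
ILK	ACTIVATION	JUND
TGFB1	ACTIVATION	JUND
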