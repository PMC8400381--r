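## table: WT
## perturbation:
## clamps:
state	TNF	IL6	TGFB1	JUN	FOS	JUND	NFKBIA	DAXX	ILK	NFKB1	MAP2K1	MAPK1	MAPK14
ss1	0	0	0	0	0	0	0	0	0	0	0	0	0
ss2	0	1	0	1	1	1	1	0	1	1	1	1	1
ss3	0	1	1	1	1	1	1	1	1	1	1	1	1
ss4	1	1	0	1	1	1	1	0	1	1	1	1	1
ss5	1	1	1	1	1	1	1	1	1	1	1	1	1
## table: KO_MAPK1_MAPK14
## perturbation: MAPK1=0,MAPK14=0
## clamps: TNF=0
state	TNF	IL6	TGFB1	JUN	FOS	JUND	NFKBIA	DAXX	ILK	NFKB1	MAP2K1	MAPK1	MAPK14
ss1	0	0	0	0	0	0	0	0	0	0	0	0	0
ss2	0	1	0	1	1	1	1	0	1	1	1	0	0
ss3	0	1	1	1	1	1	1	1	1	1	1	0	0
## table: KO_DAXX_ILK_MAP2K1
## perturbation: DAXX=0,ILK=0,MAP2K1=0
## clamps: TNF=0
state	TNF	IL6	TGFB1	JUN	FOS	JUND	NFKBIA	DAXX	ILK	NFKB1	MAP2K1	MAPK1	MAPK14
ss1	0	0	0	0	0	0	0	0	0	0	0	0	0
ss2	0	1	0	0	0	0	1	0	0	1	0	0	0
ss3	0	1	1	1	1	1	1	0	0	1	0	0	1
## table: KO_DAXX_NFKB1
## perturbation: DAXX=0,NFKB1=0
## clamps: TNF=0
state	TNF	IL6	TGFB1	JUN	FOS	JUND	NFKBIA	DAXX	ILK	NFKB1	MAP2K1	MAPK1	MAPK14
ss1	0	0	0	0	0	0	0	0	0	0	0	0	0
ss2	0	1	0	1	1	1	1	0	1	0	1	1	1
ss3	0	1	1	1	1	1	1	0	1	0	1	1	1
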