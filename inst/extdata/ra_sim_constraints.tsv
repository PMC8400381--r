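## table: SIM_KO_MAPK1_MAPK14_IL6
## perturbation: MAPK1=0,MAPK14=0
## clamps: TNF=0,IL6=1
state	JUN	FOS	JUND	NFKBIA
on	1	1	1	1
## table: SIM_KO_MAPK1_MAPK14_TNF
## perturbation: MAPK1=0,MAPK14=0
## clamps: TNF=1
state	JUN	FOS	JUND	NFKBIA
on	1	1	1	1
## table: SIM_KO_MAPK1_MAPK14_TGFB1
## perturbation: MAPK1=0,MAPK14=0
## clamps: TNF=0,TGFB1=1
state	JUN	FOS	JUND	NFKBIA
on	1	1	1	1
## table: SIM_KO_DAXX_ILK_MAP2K1_IL6
## perturbation: DAXX=0,ILK=0,MAP2K1=0
## clamps: TNF=0,IL6=1,TGFB1=0
state	JUN	FOS	JUND	NFKBIA
nfkbia_only	0	0	0	1
## table: SIM_KO_DAXX_ILK_MAP2K1_TNF
## perturbation: DAXX=0,ILK=0,MAP2K1=0
## clamps: TNF=1
state	JUN	FOS	JUND	NFKBIA
on	1	1	1	1
## table: SIM_KO_DAXX_ILK_MAP2K1_TGFB1
## perturbation: DAXX=0,ILK=0,MAP2K1=0
## clamps: TNF=0,TGFB1=1
state	JUN	FOS	JUND	NFKBIA
on	1	1	1	1
## table: SIM_KO_DAXX_NFKB1_IL6
## perturbation: DAXX=0,NFKB1=0
## clamps: TNF=0,IL6=1
state	JUN	FOS	JUND	NFKBIA
on	1	1	1	1
## table: SIM_KO_DAXX_NFKB1_TNF
## perturbation: DAXX=0,NFKB1=0
## clamps: TNF=1
state	JUN	FOS	JUND	NFKBIA
on	1	1	1	1
## table: SIM_KO_DAXX_NFKB1_TGFB1
## perturbation: DAXX=0,NFKB1=0
## clamps: TNF=0,TGFB1=1
state	JUN	FOS	JUND	NFKBIA
on	1	1	1	1
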