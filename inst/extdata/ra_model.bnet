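DAXX, TGFB1
FOS, ILK | MAPK14 | TGFB1
IL6, IL6 | NFKB1 | TNF
ILK, IL6
JUN, ILK | MAPK14 | TGFB1
JUND, ILK | MAPK14 | TGFB1
MAP2K1, ILK
MAPK1, MAP2K1
MAPK14, MAP2K1 | TGFB1 | TNF
NFKB1, DAXX | IL6 | MAPK14
NFKBIA, MAPK14 | NFKB1
TGFB1, IL6 & TGFB1
TNF, TNF
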