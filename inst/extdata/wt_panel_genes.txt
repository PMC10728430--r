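DICER1
IGF2
TP53
WT1
ASXL1
BRCA2
CDC73
FBXW7
PIK3CA
BLM
BUB1B
CTR9
DIS3L2
GPC3
KDM3B
NYNRIN
PALB2
REST
TRIP13
TRIM28
TRIM37
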