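gene	rho_liver	rho_wat	level
MMP9	NA	-0.76	3
RETN	NA	-0.70	3
CAT	-0.69	NA	1
F7	-0.68	NA	1
HP	0.85	NA	3
IGFBP2	-0.65	NA	2
IL18BP	0.75	NA	3
KRT18	0.79	NA	2
LDLR	-0.64	NA	3
LEPR	0.64	NA	3
LIPC	-0.65	NA	1
LRG1	0.63	NA	2
MBL2	-0.67	NA	3
PCSK9	-0.83	NA	1
SAA1	0.82	NA	3
SERPINA1	-0.63	NA	3
SERPINA3	0.77	NA	3
SERPINC1	-0.64	NA	3
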