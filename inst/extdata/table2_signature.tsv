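# cutoff: -0.13
gene_a	gene_b	coefficient
FGF9	MICB	0.2288
CMKLR1	BIRC5	0.1965
VIPR2	GIPR	0.3493
ELANE	IL9R	0.2896
GHR	FLT4	0.0652
ELANE	ANGPTL6	0.0617
PCSK2	FGF1	0.0177
RORB	GALR2	0.2577
EDNRB	AGER	0.0772
LCN6	TNFSF11	0.1041
MASP1	CSF2	0.1981
AHNAK	PSMD8	0.2832
IL16	APOBEC3H	0.0421
PDGFRA	VAV2	0.0141
FGF9	CST4	0.0840
GHR	LHB	0.0237
LCN6	IL13RA2	0.3899
OGN	NOX4	0.0529
SFTPD	ESM1	0.3064
TNC	SPP1	0.2258
CMTM5	MPL	0.1306
LTBP4	VAV2	0.1395
FGF13	CST4	0.0819
NR2F1	ESM1	0.0037
NR2F1	TCF7L2	0.1656
PIK3R3	RAC3	-0.1612
BMP5	OXTR	-0.2999
HLA-DOA	RAC3	-0.1058
NTF3	NOX4	-0.1384
PRF1	RAC3	-0.1295
IL10RA	TOR2A	-0.1601
LIFR	CALCRL	-0.2448
JAK2	RAC3	-0.3199
ROBO3	ESM1	-0.6215
PRKCB	DLL4	-0.2046
RBP4	RAC3	-0.5189
PRKCB	FCGR3A	-0.2420
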