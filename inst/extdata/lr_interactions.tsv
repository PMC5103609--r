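ligand	receptor	source	pmid
SEMA3C	NRP1	axon_guidance	9331420
SEMA4D	PLXNB1	axon_guidance	10520995
SEMA3B	NRP1	axon_guidance	9331420
SHH	PTCH1	hedgehog	8906787
IHH	PTCH1	hedgehog	8906787
IHH	PTCH2	hedgehog	9811851
WNT7B	GPC3	wnt	16227623
SFRP1	FZD6	wnt	9096311
HGF	MET	kinase	1846706
EGF	EGFR	kinase	6090945
TGFA	EGFR	kinase	3486778
VEGFA	KDR	kinase	1417831
VEGFA	FLT1	kinase	1417831
VEGFB	FLT1	kinase	8637916
VEGFA	NRP1	kinase	9529250
PDGFA	PDGFRA	kinase	2554309
PDGFB	PDGFRB	kinase	2554309
IGF1	IGF1R	kinase	2877871
FGF2	FGFR1	kinase	1656221
TGFB1	TGFBR1	tgf_beta	8752209
TGFB1	ENG	tgf_beta	1326540
TGFB2	TGFBR1	tgf_beta	8752209
COL1A1	CD44	ecm	7679046
COL1A2	CD44	ecm	7679046
COL1A1	ITGA2	ecm	2467744
COL1A2	ITGA2	ecm	2467744
FN1	ITGA3	ecm	2138017
FN1	ITGB6	ecm	2544585
FN1	ITGA5	ecm	2544585
LAMB1	ITGA6	ecm	2544585
EFNA1	EPHA2	ephrin	7973638
EFNB2	EPHB4	ephrin	8755474
EFNB1	EPHB2	ephrin	8755474
CXCL12	CXCR4	gpcr	8752280
CCL2	CCR2	gpcr	8642344
EDN1	EDNRA	gpcr	2175397
ANGPT1	TEK	kinase	8980223
ANGPT2	TEK	kinase	9204896
DLL4	NOTCH1	notch	10958687
JAG1	NOTCH1	notch	7697721
KITLG	KIT	kinase	1689412
CSF1	CSF1R	kinase	2420009
IL6	IL6R	cytokine	3257574
LIF	LIFR	cytokine	1849459
BMP2	BMPR1A	tgf_beta	7791754
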