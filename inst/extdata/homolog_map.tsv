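mouse_gene	human_gene
Sema3c	SEMA3C
Sema4d	SEMA4D
Sema3b	SEMA3B
Nrp1	NRP1
Plxnb1	PLXNB1
Shh	SHH
Ihh	IHH
Ptch1	PTCH1
Ptch2	PTCH2
Wnt7b	WNT7B
Gpc3	GPC3
Sfrp1	SFRP1
Fzd6	FZD6
Hgf	HGF
Met	MET
Egf	EGF
Tgfa	TGFA
Egfr	EGFR
Vegfa	VEGFA
Kdr	KDR
Flt1	FLT1
Vegfb	VEGFB
Pdgfa	PDGFA
Pdgfra	PDGFRA
Pdgfb	PDGFB
Pdgfrb	PDGFRB
Igf1	IGF1
Igf1r	IGF1R
Fgf2	FGF2
Fgfr1	FGFR1
Tgfb1	TGFB1
Tgfbr1	TGFBR1
Eng	ENG
Tgfb2	TGFB2
Col1a1	COL1A1
Col1a2	COL1A2
Cd44	CD44
Itga2	ITGA2
Fn1	FN1
Itga3	ITGA3
Itgb6	ITGB6
Itga5	ITGA5
Lamb1	LAMB1
Itga6	ITGA6
Efna1	EFNA1
Epha2	EPHA2
Efnb2	EFNB2
Ephb4	EPHB4
Efnb1	EFNB1
Ephb2	EPHB2
Cxcl12	CXCL12
Cxcr4	CXCR4
Ccl2	CCL2
Ccr2	CCR2
Edn1	EDN1
Ednra	EDNRA
Angpt1	ANGPT1
Angpt2	ANGPT2
Tek	TEK
Dll4	DLL4
Notch1	NOTCH1
Jag1	JAG1
Kitl	KITLG
Kit	KIT
Csf1	CSF1
Csf1r	CSF1R
Il6	IL6
Il6ra	IL6R
Lif	LIF
Lifr	LIFR
Bmp2	BMP2
Bmpr1a	BMPR1A
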