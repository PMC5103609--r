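category	gene	name
GO:0005102	EFNA1	ephrin receptor binding
GO:0005102	EFNB1	ephrin receptor binding
GO:0005102	EFNB2	ephrin receptor binding
GO:0005102	EPHA2	ephrin receptor binding
GO:0005102	EPHB2	ephrin receptor binding
GO:0005102	EPHB4	ephrin receptor binding
GO:0038085	VEGFA	vascular endothelial growth factor binding
GO:0038085	VEGFB	vascular endothelial growth factor binding
GO:0038085	KDR	vascular endothelial growth factor binding
GO:0038085	FLT1	vascular endothelial growth factor binding
GO:0038085	NRP1	vascular endothelial growth factor binding
GO:0034713	TGFB1	type I transforming growth factor beta receptor binding
GO:0034713	TGFB2	type I transforming growth factor beta receptor binding
GO:0034713	TGFBR1	type I transforming growth factor beta receptor binding
GO:0005201	COL1A1	extracellular matrix structural constituent
GO:0005201	COL1A2	extracellular matrix structural constituent
GO:0005201	FN1	extracellular matrix structural constituent
GO:0005201	LAMB1	extracellular matrix structural constituent
GO:0005010	IGF1	insulin-like growth factor receptor binding
GO:0005010	IGF1R	insulin-like growth factor receptor binding
GO:0008083	EGF	growth factor activity
GO:0008083	HGF	growth factor activity
GO:0008083	FGF2	growth factor activity
GO:0008083	VEGFA	growth factor activity
GO:0008083	VEGFB	growth factor activity
GO:0008083	PDGFA	growth factor activity
GO:0008083	PDGFB	growth factor activity
GO:0008083	IGF1	growth factor activity
GO:0008083	TGFB1	growth factor activity
GO:0008083	CSF1	growth factor activity
GO:0008201	FGF2	heparin binding
GO:0008201	VEGFA	heparin binding
GO:0008201	HGF	heparin binding
GO:0008201	FN1	heparin binding
GO:0008201	SEMA3C	heparin binding
GO:0007411	SEMA3C	axon guidance
GO:0007411	SEMA3B	axon guidance
GO:0007411	SEMA4D	axon guidance
GO:0007411	NRP1	axon guidance
GO:0007411	PLXNB1	axon guidance
GO:0007411	EFNA1	axon guidance
GO:0007411	EPHA2	axon guidance
GO:0016477	CXCL12	cell migration
GO:0016477	CCL2	cell migration
GO:0016477	CD44	cell migration
GO:0016477	ITGA2	cell migration
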