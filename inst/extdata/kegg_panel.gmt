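hsa04210	APO apoptosis	TP53	BAX	BCL2	CASP3	CASP8	CASP9	FAS	APAF1	BID	CYCS
hsa03022	BTF basal transcription factors	GTF2A1	GTF2B	GTF2E1	GTF2F1	GTF2H1	TAF1	TAF4	TBP
hsa04110	CCY cell cycle	CDK1	CDK2	CDK4	CCNB1	CCND1	CCNE1	CDC20	RB1	E2F1	WEE1
hsa04062	CSP chemokine signaling	CCL2	CCL5	CXCL8	CXCR4	CCR5	GNAI1	STAT3	JAK2	PIK3CA
hsa00190	OXP oxidative phosphorylation	NDUFA1	NDUFB1	SDHA	SDHB	UQCRC1	COX4I1	COX5A	ATP5F1A	ATP5F1B
hsa05211	RCC renal cell carcinoma	VHL	HIF1A	EPAS1	MET	VEGFA	EGLN3	TGFA	PDGFB
hsa03020	RPO RNA polymerase	POLR2A	POLR2B	POLR2C	POLR1A	POLR1B	POLR3A	POLR3B
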