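region	gene
group1&group2&group3	MET
group1&group2&group3	SMAD7
group1&group2&group3	EZH2
group1&group2&group3	TERT
group1&group2&group3	IL6
group1&group2	TLR4
group1&group2	MTOR
group1&group2	IGF1
group1&group2	ZEB1
group1&group2	SOX4
group1&group2	PTBP2
group1&group2	BIRC5
group1&group2	CCNE1
group1&group2	RHOB
group1&group2	MMP16
group1&group2	IGF1R
group1&group2	MYC
group1&group2	PXK
group1&group2	SOCS1
group1&group2	PBX3
group1&group2	PRKAA1
group1&group2	CFTR
group1&group2	FBXW7
group1&group3	ROCK1
group1&group3	KCNJ6
group1&group3	PTEN
group1&group3	TGFBR2
group1&group3	HOTAIR
group1&group3	PLEKHA1
group1&group3	ERBB2
group1&group3	FGA
group1&group3	CDH1
group1&group3	PPP2R5E
group1&group3	FGG
group1&group3	IRS1
group1&group3	RECK
group1&group3	DDX3X
group1&group3	FGB
group1&group3	HLA-G
group1&group3	WWP1
group1&group3	RB1
group1&group3	TCEAL1
group1&group3	HSP90AA1
group1&group3	ZFX
group2&group3	GIT1
group2&group3	NPM3
group2&group3	BRCA1
group2&group3	CHUK
group2&group3	STAT3
group2&group3	SP1
group2&group3	FOXO3
group2&group3	VEGFA
group2&group3	E2F1
group2&group3	MEF2C
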