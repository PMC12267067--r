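melanoma	synthetic stand-in for a melanoma pathway gene list	BRAF	CCND1	CDH1	KRAS	NRAS	MITF	CDKN2A	CDK4	MDM2	TP53	PTEN	MAP2K1	PIK3CA	EGF	FGF2
breast_cancer	synthetic stand-in for a breast cancer pathway gene list	BRAF	CCND1	CDH1	KRAS	ESR1	BRCA1	BRCA2	ERBB2	TP53	PTEN	GATA3	PGR	NOTCH1	FGFR1	MYC	AKT1
thyroid_cancer	synthetic stand-in for a thyroid cancer pathway gene list	BRAF	CCND1	CDH1	KRAS	RET	NTRK1	PAX8	PPARG	TP53	MAP2K2	HRAS	TPM3
gastric_cancer	synthetic stand-in for a gastric cancer pathway gene list	BRAF	CCND1	CDH1	KRAS	ERBB2	MET	FGFR2	TP53	APC	CTNNB1	SMAD4	PIK3CA	MYC	ABL1
esr1_associated	synthetic stand-in for an ESR1 interaction neighbourhood	BRAF	CCND1	CDH1	KRAS	ESR1	FOXA1	GATA3	PGR	GREB1	NCOA3	SRC	JUN	SP1	EP300	CTNNB1	AKT1
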