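TP53	tumor suppressor signalling	TP53	ATM	CHEK2	RB1	CDKN2A
WNT	Wnt/beta-catenin	CTNNB1	APC	AXIN1	GSK3B
RTK-RAS	receptor tyrosine kinase / RAS	ERBB2	NF1	KRAS	NTRK3	BRAF
NOTCH	Notch signalling	NOTCH1	NOTCH2	NOTCH3	CREBBP	SPEN
Chromatin	chromatin modifiers	ARID1A	EZH2	RBM10	GLI3
Telomere	telomere maintenance	TERT
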