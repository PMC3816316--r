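gene	source	unit	rnaseq_log2_fc	qpcr_log2_fc
TRAF1	AceView	TPM	3.029	2.862
FANCD2	AceView	TPM	-0.782	-1.050
CELF1	AceView	TPM	-0.138	-0.202
TRAF1	H-InvDB	TPM	3.034	2.862
FANCD2	H-InvDB	TPM	-0.687	-1.050
CELF1	H-InvDB	TPM	-0.202	-0.202
TRAF1	Ensembl	TPM	3.025	2.862
FANCD2	Ensembl	TPM	-0.888	-1.050
CELF1	Ensembl	TPM	-0.098	-0.202
TRAF1	Vega	TPM	2.998	2.862
FANCD2	Vega	TPM	-0.856	-1.050
CELF1	Vega	TPM	-0.098	-0.202
TRAF1	UCSC	TPM	2.934	2.862
FANCD2	UCSC	TPM	-0.840	-1.050
CELF1	UCSC	TPM	-0.239	-0.202
TRAF1	RefSeq	TPM	2.922	2.862
FANCD2	RefSeq	TPM	-0.840	-1.050
CELF1	RefSeq	TPM	-0.275	-0.202
TRAF1	AceView	FPKM	3.874	2.862
FANCD2	AceView	FPKM	0.057	-1.050
CELF1	AceView	FPKM	0.642	-0.202
TRAF1	H-InvDB	FPKM	3.845	2.862
FANCD2	H-InvDB	FPKM	0.057	-1.050
CELF1	H-InvDB	FPKM	0.516	-0.202
TRAF1	Ensembl	FPKM	3.797	2.862
FANCD2	Ensembl	FPKM	-0.345	-1.050
CELF1	Ensembl	FPKM	0.595	-0.202
TRAF1	Vega	FPKM	3.719	2.862
FANCD2	Vega	FPKM	-0.322	-1.050
CELF1	Vega	FPKM	0.585	-0.202
TRAF1	UCSC	FPKM	3.677	2.862
FANCD2	UCSC	FPKM	-0.202	-1.050
CELF1	UCSC	FPKM	0.390	-0.202
TRAF1	RefSeq	FPKM	3.674	2.862
FANCD2	RefSeq	FPKM	-0.151	-1.050
CELF1	RefSeq	FPKM	0.356	-0.202
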