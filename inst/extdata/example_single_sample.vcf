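##fileformat=VCFv4.2
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=CDOT,Number=1,Type=String,Description="HGVS coding change">
##INFO=<ID=PDOT,Number=1,Type=String,Description="HGVS protein change">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AF,Number=A,Type=Float,Description="Allele fraction">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	PLASMA1
chr17	7577534	.	C	T	100	PASS	GENE=TP53;CDOT=c.743G>A;PDOT=p.R248Q	GT:AF	0/1:0.0103
chr5	112175240	.	CA	C	80	PASS	GENE=APC	GT:AF	0/1:0.0042
chr7	151945072	.	G	A,C	60	PASS	GENE=KMT2C	GT:AF	0/1:0.0031,0.0012
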