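chr1	demo	exon	101	200	.	+	.	gene_id "g1"; transcript_id "g1.t1"; gene_name "ALPHA"; gene_biotype "protein_coding";
chr1	demo	exon	301	400	.	+	.	gene_id "g1"; transcript_id "g1.t1"; gene_name "ALPHA"; gene_biotype "protein_coding";
chr1	demo	exon	501	600	.	+	.	gene_id "g1"; transcript_id "g1.t1"; gene_name "ALPHA"; gene_biotype "protein_coding";
chr1	demo	CDS	131	200	.	+	0	gene_id "g1"; transcript_id "g1.t1"; gene_name "ALPHA"; gene_biotype "protein_coding";
chr1	demo	CDS	301	370	.	+	2	gene_id "g1"; transcript_id "g1.t1"; gene_name "ALPHA"; gene_biotype "protein_coding";
chr1	demo	exon	101	200	.	+	.	gene_id "g1"; transcript_id "g1.t2"; gene_name "ALPHA"; gene_biotype "protein_coding";
chr1	demo	exon	501	600	.	+	.	gene_id "g1"; transcript_id "g1.t2"; gene_name "ALPHA"; gene_biotype "protein_coding";
chr1	demo	exon	2001	2100	.	-	.	gene_id "g2"; transcript_id "g2.t1"; gene_name "BETA"; gene_biotype "protein_coding";
chr1	demo	exon	2201	2300	.	-	.	gene_id "g2"; transcript_id "g2.t1"; gene_name "BETA"; gene_biotype "protein_coding";
chr1	demo	exon	2401	2500	.	-	.	gene_id "g2"; transcript_id "g2.t1"; gene_name "BETA"; gene_biotype "protein_coding";
chr1	demo	exon	2001	2100	.	-	.	gene_id "g2"; transcript_id "g2.t2"; gene_name "BETA"; gene_biotype "protein_coding";
chr1	demo	exon	2401	2500	.	-	.	gene_id "g2"; transcript_id "g2.t2"; gene_name "BETA"; gene_biotype "protein_coding";
chr2	demo	exon	501	600	.	+	.	gene_id "g3"; transcript_id "g3.t1"; gene_name "GAMMA"; gene_biotype "lincRNA";
chr2	demo	exon	701	800	.	+	.	gene_id "g3"; transcript_id "g3.t1"; gene_name "GAMMA"; gene_biotype "lincRNA";
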