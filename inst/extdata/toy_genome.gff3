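##gff-version 3
##sequence-region chr1 1 5000
chr1	toytool	gene	100	400	.	+	.	ID=gene001;locus_tag=TOY_0001
chr1	toytool	CDS	500	800	.	-	.	ID=cds001;locus_tag=TOY_0002
chr1	toytool	tRNA	900	1000	.	+	.	ID=trna001;locus_tag=TOY_0003
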