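chr1	toy	exon	201	410	.	+	.	gene_id "HRAS"; transcript_id "HRAS.t1"; gene_name "HRAS";
chr1	toy	CDS	231	410	.	+	.	gene_id "HRAS"; transcript_id "HRAS.t1"; gene_name "HRAS";
chr1	toy	exon	531	740	.	+	.	gene_id "HRAS"; transcript_id "HRAS.t1"; gene_name "HRAS";
chr1	toy	CDS	531	740	.	+	.	gene_id "HRAS"; transcript_id "HRAS.t1"; gene_name "HRAS";
chr1	toy	exon	861	1070	.	+	.	gene_id "HRAS"; transcript_id "HRAS.t1"; gene_name "HRAS";
chr1	toy	CDS	861	1040	.	+	.	gene_id "HRAS"; transcript_id "HRAS.t1"; gene_name "HRAS";
chr1	toy	exon	1371	1579	.	-	.	gene_id "KRAS"; transcript_id "KRAS.t1"; gene_name "KRAS";
chr1	toy	CDS	1401	1579	.	-	.	gene_id "KRAS"; transcript_id "KRAS.t1"; gene_name "KRAS";
chr1	toy	exon	1700	1908	.	-	.	gene_id "KRAS"; transcript_id "KRAS.t1"; gene_name "KRAS";
chr1	toy	CDS	1700	1908	.	-	.	gene_id "KRAS"; transcript_id "KRAS.t1"; gene_name "KRAS";
chr1	toy	exon	2029	2237	.	-	.	gene_id "KRAS"; transcript_id "KRAS.t1"; gene_name "KRAS";
chr1	toy	CDS	2029	2207	.	-	.	gene_id "KRAS"; transcript_id "KRAS.t1"; gene_name "KRAS";
chr1	toy	exon	2538	2858	.	+	.	gene_id "TP53"; transcript_id "TP53.t1"; gene_name "TP53";
chr1	toy	CDS	2568	2858	.	+	.	gene_id "TP53"; transcript_id "TP53.t1"; gene_name "TP53";
chr1	toy	exon	2979	3299	.	+	.	gene_id "TP53"; transcript_id "TP53.t1"; gene_name "TP53";
chr1	toy	CDS	2979	3299	.	+	.	gene_id "TP53"; transcript_id "TP53.t1"; gene_name "TP53";
chr1	toy	exon	3420	3740	.	+	.	gene_id "TP53"; transcript_id "TP53.t1"; gene_name "TP53";
chr1	toy	CDS	3420	3710	.	+	.	gene_id "TP53"; transcript_id "TP53.t1"; gene_name "TP53";
chr1	toy	exon	4041	4311	.	+	.	gene_id "EGFR"; transcript_id "EGFR.t1"; gene_name "EGFR";
chr1	toy	CDS	4071	4311	.	+	.	gene_id "EGFR"; transcript_id "EGFR.t1"; gene_name "EGFR";
chr1	toy	exon	4432	4702	.	+	.	gene_id "EGFR"; transcript_id "EGFR.t1"; gene_name "EGFR";
chr1	toy	CDS	4432	4702	.	+	.	gene_id "EGFR"; transcript_id "EGFR.t1"; gene_name "EGFR";
chr1	toy	exon	4823	5093	.	+	.	gene_id "EGFR"; transcript_id "EGFR.t1"; gene_name "EGFR";
chr1	toy	CDS	4823	5063	.	+	.	gene_id "EGFR"; transcript_id "EGFR.t1"; gene_name "EGFR";
chr1	toy	exon	5394	5654	.	+	.	gene_id "CTNNB1"; transcript_id "CTNNB1.t1"; gene_name "CTNNB1";
chr1	toy	CDS	5424	5654	.	+	.	gene_id "CTNNB1"; transcript_id "CTNNB1.t1"; gene_name "CTNNB1";
chr1	toy	exon	5775	6035	.	+	.	gene_id "CTNNB1"; transcript_id "CTNNB1.t1"; gene_name "CTNNB1";
chr1	toy	CDS	5775	6035	.	+	.	gene_id "CTNNB1"; transcript_id "CTNNB1.t1"; gene_name "CTNNB1";
chr1	toy	exon	6156	6416	.	+	.	gene_id "CTNNB1"; transcript_id "CTNNB1.t1"; gene_name "CTNNB1";
chr1	toy	CDS	6156	6386	.	+	.	gene_id "CTNNB1"; transcript_id "CTNNB1.t1"; gene_name "CTNNB1";
chr2	toy	exon	201	861	.	+	.	gene_id "BRAF"; transcript_id "BRAF.t1"; gene_name "BRAF";
chr2	toy	CDS	231	861	.	+	.	gene_id "BRAF"; transcript_id "BRAF.t1"; gene_name "BRAF";
chr2	toy	exon	982	1642	.	+	.	gene_id "BRAF"; transcript_id "BRAF.t1"; gene_name "BRAF";
chr2	toy	CDS	982	1642	.	+	.	gene_id "BRAF"; transcript_id "BRAF.t1"; gene_name "BRAF";
chr2	toy	exon	1763	2423	.	+	.	gene_id "BRAF"; transcript_id "BRAF.t1"; gene_name "BRAF";
chr2	toy	CDS	1763	2393	.	+	.	gene_id "BRAF"; transcript_id "BRAF.t1"; gene_name "BRAF";
chr2	toy	exon	2724	2933	.	+	.	gene_id "NRAS"; transcript_id "NRAS.t1"; gene_name "NRAS";
chr2	toy	CDS	2754	2933	.	+	.	gene_id "NRAS"; transcript_id "NRAS.t1"; gene_name "NRAS";
chr2	toy	exon	3054	3263	.	+	.	gene_id "NRAS"; transcript_id "NRAS.t1"; gene_name "NRAS";
chr2	toy	CDS	3054	3263	.	+	.	gene_id "NRAS"; transcript_id "NRAS.t1"; gene_name "NRAS";
chr2	toy	exon	3384	3593	.	+	.	gene_id "NRAS"; transcript_id "NRAS.t1"; gene_name "NRAS";
chr2	toy	CDS	3384	3563	.	+	.	gene_id "NRAS"; transcript_id "NRAS.t1"; gene_name "NRAS";
chr2	toy	exon	3894	4474	.	-	.	gene_id "SMO"; transcript_id "SMO.t1"; gene_name "SMO";
chr2	toy	CDS	3924	4474	.	-	.	gene_id "SMO"; transcript_id "SMO.t1"; gene_name "SMO";
chr2	toy	exon	4595	5175	.	-	.	gene_id "SMO"; transcript_id "SMO.t1"; gene_name "SMO";
chr2	toy	CDS	4595	5175	.	-	.	gene_id "SMO"; transcript_id "SMO.t1"; gene_name "SMO";
chr2	toy	exon	5296	5876	.	-	.	gene_id "SMO"; transcript_id "SMO.t1"; gene_name "SMO";
chr2	toy	CDS	5296	5846	.	-	.	gene_id "SMO"; transcript_id "SMO.t1"; gene_name "SMO";
chr2	toy	exon	6177	6397	.	+	.	gene_id "PTEN"; transcript_id "PTEN.t1"; gene_name "PTEN";
chr2	toy	CDS	6207	6397	.	+	.	gene_id "PTEN"; transcript_id "PTEN.t1"; gene_name "PTEN";
chr2	toy	exon	6518	6738	.	+	.	gene_id "PTEN"; transcript_id "PTEN.t1"; gene_name "PTEN";
chr2	toy	CDS	6518	6738	.	+	.	gene_id "PTEN"; transcript_id "PTEN.t1"; gene_name "PTEN";
chr2	toy	exon	6859	7079	.	+	.	gene_id "PTEN"; transcript_id "PTEN.t1"; gene_name "PTEN";
chr2	toy	CDS	6859	7049	.	+	.	gene_id "PTEN"; transcript_id "PTEN.t1"; gene_name "PTEN";
chr2	toy	exon	7380	7650	.	-	.	gene_id "SMAD4"; transcript_id "SMAD4.t1"; gene_name "SMAD4";
chr2	toy	CDS	7410	7650	.	-	.	gene_id "SMAD4"; transcript_id "SMAD4.t1"; gene_name "SMAD4";
chr2	toy	exon	7771	8041	.	-	.	gene_id "SMAD4"; transcript_id "SMAD4.t1"; gene_name "SMAD4";
chr2	toy	CDS	7771	8041	.	-	.	gene_id "SMAD4"; transcript_id "SMAD4.t1"; gene_name "SMAD4";
chr2	toy	exon	8162	8432	.	-	.	gene_id "SMAD4"; transcript_id "SMAD4.t1"; gene_name "SMAD4";
chr2	toy	CDS	8162	8402	.	-	.	gene_id "SMAD4"; transcript_id "SMAD4.t1"; gene_name "SMAD4";
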