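chr1	quadte	exon	401	900	.	+	.	gene_id "gene_utr5_canonical_001"; transcript_id "gene_utr5_canonical_001.t1";
chr1	quadte	exon	1051	1650	.	+	.	gene_id "gene_utr5_canonical_001"; transcript_id "gene_utr5_canonical_001.t1";
chr1	quadte	CDS	601	900	.	+	0	gene_id "gene_utr5_canonical_001"; transcript_id "gene_utr5_canonical_001.t1";
chr1	quadte	CDS	1051	1350	.	+	0	gene_id "gene_utr5_canonical_001"; transcript_id "gene_utr5_canonical_001.t1";
chr1	quadte	exon	2051	2650	.	-	.	gene_id "gene_utr5_bulge_001"; transcript_id "gene_utr5_bulge_001.t1";
chr1	quadte	exon	2801	3300	.	-	.	gene_id "gene_utr5_bulge_001"; transcript_id "gene_utr5_bulge_001.t1";
chr1	quadte	CDS	2351	2650	.	-	0	gene_id "gene_utr5_bulge_001"; transcript_id "gene_utr5_bulge_001.t1";
chr1	quadte	CDS	2801	3100	.	-	0	gene_id "gene_utr5_bulge_001"; transcript_id "gene_utr5_bulge_001.t1";
chr1	quadte	exon	3701	4200	.	+	.	gene_id "gene_utr5_two_quartet_001"; transcript_id "gene_utr5_two_quartet_001.t1";
chr1	quadte	exon	4351	4950	.	+	.	gene_id "gene_utr5_two_quartet_001"; transcript_id "gene_utr5_two_quartet_001.t1";
chr1	quadte	CDS	3901	4200	.	+	0	gene_id "gene_utr5_two_quartet_001"; transcript_id "gene_utr5_two_quartet_001.t1";
chr1	quadte	CDS	4351	4650	.	+	0	gene_id "gene_utr5_two_quartet_001"; transcript_id "gene_utr5_two_quartet_001.t1";
chr1	quadte	exon	5351	5950	.	-	.	gene_id "gene_cds_bound_001"; transcript_id "gene_cds_bound_001.t1";
chr1	quadte	exon	6101	6600	.	-	.	gene_id "gene_cds_bound_001"; transcript_id "gene_cds_bound_001.t1";
chr1	quadte	CDS	5651	5950	.	-	0	gene_id "gene_cds_bound_001"; transcript_id "gene_cds_bound_001.t1";
chr1	quadte	CDS	6101	6400	.	-	0	gene_id "gene_cds_bound_001"; transcript_id "gene_cds_bound_001.t1";
chr1	quadte	exon	7001	7500	.	+	.	gene_id "gene_utr3_are_001"; transcript_id "gene_utr3_are_001.t1";
chr1	quadte	exon	7651	8250	.	+	.	gene_id "gene_utr3_are_001"; transcript_id "gene_utr3_are_001.t1";
chr1	quadte	CDS	7201	7500	.	+	0	gene_id "gene_utr3_are_001"; transcript_id "gene_utr3_are_001.t1";
chr1	quadte	CDS	7651	7950	.	+	0	gene_id "gene_utr3_are_001"; transcript_id "gene_utr3_are_001.t1";
chr2	quadte	exon	401	1000	.	-	.	gene_id "gene_control_001"; transcript_id "gene_control_001.t1";
chr2	quadte	exon	1151	1650	.	-	.	gene_id "gene_control_001"; transcript_id "gene_control_001.t1";
chr2	quadte	CDS	701	1000	.	-	0	gene_id "gene_control_001"; transcript_id "gene_control_001.t1";
chr2	quadte	CDS	1151	1450	.	-	0	gene_id "gene_control_001"; transcript_id "gene_control_001.t1";
chr2	quadte	exon	2051	2550	.	+	.	gene_id "gene_control_002"; transcript_id "gene_control_002.t1";
chr2	quadte	exon	2701	3300	.	+	.	gene_id "gene_control_002"; transcript_id "gene_control_002.t1";
chr2	quadte	CDS	2251	2550	.	+	0	gene_id "gene_control_002"; transcript_id "gene_control_002.t1";
chr2	quadte	CDS	2701	3000	.	+	0	gene_id "gene_control_002"; transcript_id "gene_control_002.t1";
chr2	quadte	exon	3701	4300	.	-	.	gene_id "gene_control_003"; transcript_id "gene_control_003.t1";
chr2	quadte	exon	4451	4950	.	-	.	gene_id "gene_control_003"; transcript_id "gene_control_003.t1";
chr2	quadte	CDS	4001	4300	.	-	0	gene_id "gene_control_003"; transcript_id "gene_control_003.t1";
chr2	quadte	CDS	4451	4750	.	-	0	gene_id "gene_control_003"; transcript_id "gene_control_003.t1";
chr2	quadte	exon	5351	5850	.	+	.	gene_id "gene_control_004"; transcript_id "gene_control_004.t1";
chr2	quadte	exon	6001	6600	.	+	.	gene_id "gene_control_004"; transcript_id "gene_control_004.t1";
chr2	quadte	CDS	5551	5850	.	+	0	gene_id "gene_control_004"; transcript_id "gene_control_004.t1";
chr2	quadte	CDS	6001	6300	.	+	0	gene_id "gene_control_004"; transcript_id "gene_control_004.t1";
chr2	quadte	exon	7001	7600	.	-	.	gene_id "gene_control_005"; transcript_id "gene_control_005.t1";
chr2	quadte	exon	7751	8250	.	-	.	gene_id "gene_control_005"; transcript_id "gene_control_005.t1";
chr2	quadte	CDS	7301	7600	.	-	0	gene_id "gene_control_005"; transcript_id "gene_control_005.t1";
chr2	quadte	CDS	7751	8050	.	-	0	gene_id "gene_control_005"; transcript_id "gene_control_005.t1";
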