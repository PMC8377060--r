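{"genes":{"gene_id":["gene_utr5_canonical_001","gene_utr5_bulge_001","gene_utr5_two_quartet_001","gene_cds_bound_001","gene_utr3_are_001","gene_control_001","gene_control_002","gene_control_003","gene_control_004","gene_control_005"],"role":["utr5_canonical","utr5_bulge","utr5_two_quartet","cds_bound","utr3_are","control","control","control","control","control"],"chrom":["chr1","chr1","chr1","chr1","chr1","chr2","chr2","chr2","chr2","chr2"],"strand":["+","-","+","-","+","-","+","-","+","-"],"gene_start":[400,2050,3700,5350,7000,400,2050,3700,5350,7000],"gene_end":[1650,3300,4950,6600,8250,1650,3300,4950,6600,8250],"bound_region":["5'UTR","5'UTR","5'UTR","CDS","3'UTR",null,null,null,null,null],"rg4_subtype":["canonical","bulge","two_quartet",null,null,null,null,null,null,null],"are_class":[null,null,null,null,"class2",null,null,null,null,null],"te_planted":["down","down","down","unchanged","unchanged","unchanged","unchanged","unchanged","unchanged","unchanged"],"mrna_planted":["unchanged","unchanged","unchanged","unchanged","unchanged","unchanged","unchanged","unchanged","unchanged","unchanged"],"stringent":[true,true,true,false,false,false,false,false,false,false]},"sites":{"gene_id":["gene_utr5_canonical_001","gene_utr5_bulge_001","gene_utr5_two_quartet_001","gene_cds_bound_001","gene_utr3_are_001"],"chrom":["chr1","chr1","chr1","chr1","chr1"],"struct_genomic_start":[492,3192,3794,6235,8095],"struct_genomic_end":[507,3208,3805,6250,8104],"struct_tx_start":[92,92,94,350,945],"struct_tx_end":[107,108,105,365,954],"peak_start":[400,3100,3700,6200,8000],"peak_end":[600,3300,3900,6300,8200]},"config":{"seed":42,"n_genes":10,"utr5_len":200,"cds_len":600,"utr3_len":300,"intron_len":150,"spacer":400,"genes_per_chrom":5,"n_utr5_canonical":1,"n_utr5_bulge":1,"n_utr5_two_quartet":1,"n_cds":1,"n_utr3_are":1,"ztnb_r":2,"ztnb_p":0.3,"bin":100,"enrichment":10,"fpkm_meanlog":2.99573227355399,"fpkm_sdlog":1,"sigma_rep":0.1,"te_down_fraction":0.8,"delta_te_down":0.4,"n_mrna_up":0,"n_mrna_down":0,"mrna_up_fc":2.5,"mrna_down_fc":0.4}}
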