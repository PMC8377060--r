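# small in-code fixtures shared across tests

# two-exon gene on a 500-nt chromosome; CDS spans the intron
demo_gtf_lines <- function(strand = "+") {
  attrs <- 'gene_id "g1"; transcript_id "t1";'
  c(sprintf("chrT\ttest\texon\t101\t200\t.\t%s\t.\t%s", strand, attrs),
    sprintf("chrT\ttest\texon\t301\t400\t.\t%s\t.\t%s", strand, attrs),
    sprintf("chrT\ttest\tCDS\t151\t200\t.\t%s\t0\t%s", strand, attrs),
    sprintf("chrT\ttest\tCDS\t301\t350\t.\t%s\t0\t%s", strand, attrs))
}

write_demo_gtf <- function(strand = "+") {
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  writeLines(demo_gtf_lines(strand), path)
  path
}

# FPKM table builder: one row per gene from a spec list
make_fpkm_row <- function(gene_id, total_ctrl, poly_ctrl, total_ko, poly_ko,
                          reps = c(1, 1)) {
  tibble::tibble(
    gene_id = gene_id,
    fpkm_total_ctrl_1 = total_ctrl * reps[1],
    fpkm_total_ctrl_2 = total_ctrl * reps[2],
    fpkm_polysome_ctrl_1 = poly_ctrl * reps[1],
    fpkm_polysome_ctrl_2 = poly_ctrl * reps[2],
    fpkm_total_ko_1 = total_ko * reps[1],
    fpkm_total_ko_2 = total_ko * reps[2],
    fpkm_polysome_ko_1 = poly_ko * reps[1],
    fpkm_polysome_ko_2 = poly_ko * reps[2])
}
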