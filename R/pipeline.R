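#' Run the full binding-to-translation analysis
#'
#' End-to-end driver: bins the two replicate CLIP coverage tracks, fits
#' the ZTNB background and calls peaks per replicate, intersects
#' replicates, assigns shared sites to transcript regions, computes
#' per-region densities, derives TE categories from the FPKM table,
#' builds integrated per-gene records, tallies rG4 subtypes per binding
#' site, and compares 5'UTR folding energies of TE-up/TE-down bound
#' genes against a sampled background.
#'
#' @param genome Named character vector from [read_fasta()] (or the
#'   generator).
#' @param models Named list of `transcript_model` objects.
#' @param clip_rep1,clip_rep2 Coverage tibbles (bedGraph convention).
#' @param fpkm FPKM tibble (see [read_fpkm_table()]).
#' @param bin CLIP bin size (nt).
#' @param alpha Peak significance threshold.
#' @param background_n Background gene-set size for energy comparisons.
#' @param seed Seed for the background sample.
#' @param engine Folding engine; defaults to [internal_fold_engine()].
#' @return List with `sites_rep1`, `sites_rep2`, `shared`, `coverage_cor`,
#'   `sites` (region-annotated shared sites with `sequence`), `density`,
#'   `te`, `integrated`, `tallies`, `subtype_tallies_5utr`,
#'   `are_tallies_3utr`, `kde`, `divergence`, `stringent_genes`,
#'   `background_genes`, `energies`, `energy_report`, `ztnb_rep1`,
#'   `ztnb_rep2`.
#' @export
run_pipeline <- function(genome, models, clip_rep1, clip_rep2, fpkm,
                         bin = 100L, alpha = 0.05, background_n = 1000L,
                         seed = 1L, engine = internal_fold_engine()) {
  bins1 <- bin_coverage(clip_rep1, bin = bin)
  bins2 <- bin_coverage(clip_rep2, bin = bin)
  m1 <- fit_ztnb(bins1$count[bins1$count > 0L])
  m2 <- fit_ztnb(bins2$count[bins2$count > 0L])
  sites1 <- call_peaks(bins1, m1, alpha = alpha)
  sites2 <- call_peaks(bins2, m2, alpha = alpha)
  shared <- intersect_replicates(sites1, sites2)
  cov_cor <- replicate_coverage_cor(clip_rep1, clip_rep2)

  sites <- assign_region(shared$shared, models)
  density <- region_density(sites, models)

  reps <- representative_transcripts(models)
  strand_of <- vapply(reps, function(m) m$strand, "")
  names(strand_of) <- vapply(reps, function(m) m$gene_id, "")
  sites$sequence <- vapply(seq_len(nrow(sites)), function(i) {
    st <- if (!is.na(sites$gene_id[i])) strand_of[[sites$gene_id[i]]]
          else "+"
    extract_sense_sequence(genome, sites$chrom[i], sites$start[i],
                           sites$end[i], st)
  }, "")

  te <- categorize_changes(consistency_filter(compute_te(fpkm)))
  integrated <- integrate_records(sites, te)
  tallies <- tally_by_region_and_category(integrated)
  subtype_tallies <- tally_site_subtypes(sites, sites$sequence, integrated,
                                         region = "5'UTR",
                                         category_type = "te")

  # ARE presence among 3'UTR-bound genes: scan the 3'UTR of each
  bound3 <- integrated$gene_id[integrated$bound_3utr &
                                 integrated$expressed %in% TRUE]
  are_tallies <- dplyr::bind_rows(lapply(bound3, function(gid) {
    m <- reps[[gid]]
    if (is.null(m$regions)) return(NULL)
    r3 <- m$regions[m$regions$region == "3'UTR", , drop = FALSE]
    if (nrow(r3) == 0L) return(NULL)
    s <- transcript_sequence(m, genome)
    hits <- scan_are(substr(s, r3$start + 1L, r3$end), id = gid)
    tibble::tibble(gene_id = gid, n_ares = nrow(hits),
                   classes = paste(sort(unique(hits$are_class)),
                                   collapse = ","))
  }))

  kde <- delta_density_summary(integrated)
  divergence <- divergence_classes(integrated)
  stringent <- stringent_te_down(te)

  # folding energies over 5'UTR windows of focal + background genes
  pool <- integrated$gene_id[!integrated$bound &
                               integrated$te_category %in% "unchanged" &
                               integrated$mrna_category %in% "unchanged"]
  background <- suppressWarnings(
    sample_background(pool, n = background_n, seed = seed))
  focal_sets <- list(
    te_up_5utr = integrated$gene_id[integrated$bound_5utr &
                                      integrated$te_category %in% "up"],
    te_down_5utr = integrated$gene_id[integrated$bound_5utr &
                                        integrated$te_category %in% "down"])
  energy_genes <- unique(c(unlist(focal_sets), background))
  energies <- dplyr::bind_rows(lapply(energy_genes, function(gid) {
    m <- reps[[gid]]
    if (is.null(m) || is.null(m$regions)) return(NULL)
    r5 <- m$regions[m$regions$region == "5'UTR", , drop = FALSE]
    if (nrow(r5) == 0L) return(NULL)
    s <- transcript_sequence(m, genome)
    rec <- fold_energies(substr(s, r5$start + 1L, r5$end), engine, id = gid)
    rec$gene_id <- gid
    rec
  }))
  report <- energy_report(energies, focal_sets, background)

  list(sites_rep1 = sites1, sites_rep2 = sites2, shared = shared,
       coverage_cor = cov_cor, sites = sites, density = density, te = te,
       integrated = integrated, tallies = tallies,
       subtype_tallies_5utr = subtype_tallies,
       are_tallies_3utr = are_tallies, kde = kde, divergence = divergence,
       stringent_genes = stringent, background_genes = background,
       energies = energies, energy_report = report,
       ztnb_rep1 = m1, ztnb_rep2 = m2)
}
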