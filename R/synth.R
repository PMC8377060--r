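# Synthetic study generator: a miniature transcriptome with planted rG4
# and ARE structures, ZTNB-distributed CLIP coverage with enriched peaks
# shared between two replicates, and FPKM tables with planted TE / mRNA
# effects -- all with serialised ground truth and byte-identical output
# under a fixed seed.

planted_motifs <- list(
  canonical = "GGGAGGGAGGGAGGG",
  bulge = "GGGAGGGAGGAGAGGG",
  two_quartet = "GGAGGAGGAGG",
  are_class2 = "AUUUAUUUA")

#' Configuration for the synthetic-data generator
#'
#' Defaults encode the study conditions the pipeline targets: 200 genes
#' of which 40 carry a canonical rG4 in the 5'UTR with a CLIP peak over
#' it (plus smaller bulge and two-quartet groups), 20 genes bound in the
#' CDS, 20 with a class-2 ARE plus binding in the 3'UTR; CLIP bin counts
#' follow a negative binomial background (r = 2, p = 0.3, 100-nt bins)
#' with peaks enriched 10-fold over the background mean in both
#' replicates; FPKM values are lognormal with multiplicative replicate
#' noise (sigma = 0.1 on the log scale), and 80% of the 5'UTR-rG4-bound
#' genes lose translational efficiency in KO with a planted TE fold
#' change of 0.4 (a clear TE-down under the 0.66 category threshold and
#' under the stringent log2 < -1 rule).
#'
#' @param seed Integer seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @param n_genes Number of genes.
#' @param utr5_len,cds_len,utr3_len,intron_len,spacer Region lengths (nt).
#' @param genes_per_chrom Genes laid head-to-tail per chromosome.
#' @param n_utr5_canonical,n_utr5_bulge,n_utr5_two_quartet Genes with the
#'   corresponding rG4 subtype planted in the 5'UTR and a peak over it.
#' @param n_cds Genes with a CDS peak (no planted structure).
#' @param n_utr3_are Genes with a class-2 ARE planted in the 3'UTR and a
#'   peak over it.
#' @param ztnb_r,ztnb_p Background count model parameters.
#' @param bin CLIP bin size (nt).
#' @param enrichment Peak enrichment factor over the background mean.
#' @param fpkm_meanlog,fpkm_sdlog Baseline FPKM lognormal parameters.
#' @param sigma_rep Replicate noise sd on the natural-log scale.
#' @param te_down_fraction Fraction of 5'UTR-rG4-bound genes with the
#'   planted TE loss.
#' @param delta_te_down Planted KO/Ctrl TE ratio for those genes.
#' @param n_mrna_up,n_mrna_down Unbound genes with planted mRNA changes.
#' @param mrna_up_fc,mrna_down_fc Planted mRNA fold changes.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_genes = 200L,
                             utr5_len = 200L, cds_len = 600L,
                             utr3_len = 300L, intron_len = 150L,
                             spacer = 400L, genes_per_chrom = 25L,
                             n_utr5_canonical = 40L, n_utr5_bulge = 6L,
                             n_utr5_two_quartet = 6L, n_cds = 20L,
                             n_utr3_are = 20L,
                             ztnb_r = 2, ztnb_p = 0.3, bin = 100L,
                             enrichment = 10,
                             fpkm_meanlog = log(20), fpkm_sdlog = 1,
                             sigma_rep = 0.1,
                             te_down_fraction = 0.8, delta_te_down = 0.4,
                             n_mrna_up = 10L, n_mrna_down = 10L,
                             mrna_up_fc = 2.5, mrna_down_fc = 0.4) {
  cfg <- as.list(environment())
  n_bound <- n_utr5_canonical + n_utr5_bulge + n_utr5_two_quartet +
    n_cds + n_utr3_are
  if (n_bound + n_mrna_up + n_mrna_down > n_genes) {
    stop("planted gene groups exceed n_genes")
  }
  for (m in planted_motifs) {
    if (nchar(m) + 2L > min(utr5_len, utr3_len)) {
      stop("planted structure longer than its target region")
    }
  }
  if (delta_te_down > 0.66) {
    stop("delta_te_down must be <= 0.66 for a TE-down scenario")
  }
  structure(cfg, class = "synthetic_config")
}

random_rna_seq <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# all rG4/ARE hit spans on both strands of a chromosome (genomic coords)
both_strand_hits <- function(dna) {
  rna <- as_rna(dna)
  len <- nchar(rna)
  fwd <- dplyr::bind_rows(scan_rg4(rna)[, c("start", "end")],
                          scan_are(rna)[, c("start", "end")])
  rc <- rna_revcomp(rna)
  rev_hits <- dplyr::bind_rows(scan_rg4(rc)[, c("start", "end")],
                               scan_are(rc)[, c("start", "end")])
  if (nrow(rev_hits)) {
    rev_hits <- tibble::tibble(start = len - rev_hits$end,
                               end = len - rev_hits$start)
  }
  dplyr::bind_rows(fwd, rev_hits)
}

# redraw background until the only structure hits on either strand are
# exactly the planted (protected) spans; protected positions are never
# touched, so planted ground truth stays byte-exact
clean_chromosome <- function(dna, protected, max_iter = 300L) {
  len <- nchar(dna)
  prot <- rep(FALSE, len)
  for (i in seq_len(nrow(protected))) {
    prot[(protected$start[i] + 1L):protected$end[i]] <- TRUE
  }
  keys <- paste(protected$start, protected$end)
  for (iter in seq_len(max_iter)) {
    hits <- both_strand_hits(dna)
    art <- hits[!paste(hits$start, hits$end) %in% keys, , drop = FALSE]
    if (nrow(art) == 0L) {
      # every protected span must also be detected (planted motifs)
      found <- paste(hits$start, hits$end)
      if (!all(keys %in% c(found, character(0))) && nrow(protected) > 0L) {
        stop("planted structure lost during background cleanup")
      }
      return(dna)
    }
    ch <- strsplit(dna, "")[[1]]
    for (i in seq_len(nrow(art))) {
      pos <- max(1L, art$start[i]):min(len, art$end[i] + 1L)
      pos <- pos[!prot[pos]]
      if (length(pos)) {
        ch[pos] <- sample(c("A", "C", "G", "T"), length(pos),
                          replace = TRUE)
      }
    }
    dna <- paste(ch, collapse = "")
  }
  stop("could not clean chromosome background after ", max_iter,
       " iterations")
}

# plant a motif (with single-C padding) into a sequence at offset `at`
# (0-based); returns the sequence and the motif span
plant_motif <- function(seq, motif, at) {
  padded <- paste0("C", motif, "C")
  stopifnot(at >= 1L, at + nchar(padded) - 1L <= nchar(seq))
  substr(seq, at, at + nchar(padded) - 1L) <- padded
  list(seq = seq, start = at, end = at + nchar(motif))  # 0-based motif span
}

rna_to_dna <- function(x) chartr("U", "T", x)

#' Generate the synthetic dataset
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `annotation.gtf`, `clip_rep1.bedGraph`, `clip_rep2.bedGraph`,
#'   `fpkm.tsv` and `ground_truth.json`.
#' @return List with `genome` (named DNA character vector), `models`
#'   (transcript models), `clip_rep1`/`clip_rep2` (coverage tibbles),
#'   `fpkm` (FPKM tibble), `truth` (ground-truth list with `genes` and
#'   `sites` tibbles) and `config`.
#' @export
generate_synthetic_data <- function(config = synthetic_config(),
                                    out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_synthetic_impl(config, out_dir))
}

generate_synthetic_impl <- function(cfg, out_dir) {
  roles <- c(rep("utr5_canonical", cfg$n_utr5_canonical),
             rep("utr5_bulge", cfg$n_utr5_bulge),
             rep("utr5_two_quartet", cfg$n_utr5_two_quartet),
             rep("cds_bound", cfg$n_cds),
             rep("utr3_are", cfg$n_utr3_are),
             rep("mrna_up", cfg$n_mrna_up),
             rep("mrna_down", cfg$n_mrna_down))
  roles <- c(roles, rep("control", cfg$n_genes - length(roles)))
  idx <- stats::ave(seq_along(roles), roles, FUN = seq_along)
  gene_ids <- sprintf("gene_%s_%03d", roles, idx)

  rg4_roles <- c("utr5_canonical", "utr5_bulge", "utr5_two_quartet")
  is_rg4_bound <- roles %in% rg4_roles
  n_te_down <- ceiling(cfg$te_down_fraction * sum(is_rg4_bound))
  te_down_genes <- gene_ids[is_rg4_bound][seq_len(n_te_down)]

  gene_len <- cfg$utr5_len + cfg$cds_len + cfg$intron_len + cfg$utr3_len
  exon_a_len <- cfg$utr5_len + cfg$cds_len %/% 2L
  genes <- list()
  models <- list()
  chrom_seqs <- list()
  sites_truth <- list()

  for (g in seq_along(gene_ids)) {
    role <- roles[g]
    strand <- if (g %% 2L == 0L) "-" else "+"
    chrom <- sprintf("chr%d", (g - 1L) %/% cfg$genes_per_chrom + 1L)
    pos_in_chrom <- (g - 1L) %% cfg$genes_per_chrom
    g0 <- pos_in_chrom * (gene_len + cfg$spacer) + cfg$spacer

    utr5 <- random_rna_seq(cfg$utr5_len)
    cds <- random_rna_seq(cfg$cds_len)
    utr3 <- random_rna_seq(cfg$utr3_len)
    intron <- random_rna_seq(cfg$intron_len)

    subtype <- NA_character_
    are_class <- NA_character_
    struct_tx <- NULL    # 0-based transcript-coordinate motif span
    if (role %in% rg4_roles) {
      motif <- planted_motifs[[sub("utr5_", "", role)]]
      at <- (cfg$utr5_len - nchar(motif) - 2L) %/% 2L + 1L
      p <- plant_motif(utr5, motif, at)
      utr5 <- p$seq
      subtype <- sub("utr5_", "", role)
      struct_tx <- c(p$start, p$end)
    } else if (role == "utr3_are") {
      motif <- planted_motifs$are_class2
      at <- (cfg$utr3_len - nchar(motif) - 2L) %/% 2L + 1L
      p <- plant_motif(utr3, motif, at)
      utr3 <- p$seq
      are_class <- "class2"
      struct_tx <- c(cfg$utr5_len + cfg$cds_len + p$start,
                     cfg$utr5_len + cfg$cds_len + p$end)
    } else if (role == "cds_bound") {
      # placed in the first CDS exon chunk so the peak bin stays exonic
      w <- 15L
      at <- cfg$utr5_len + cfg$cds_len %/% 4L
      struct_tx <- c(at, at + w)
    }

    mature <- paste0(utr5, cds, utr3)
    # sense-direction genomic layout: exonA | intron | exonB
    genomic_sense <- paste0(substr(mature, 1L, exon_a_len), intron,
                            substr(mature, exon_a_len + 1L, nchar(mature)))
    chunk <- rna_to_dna(
      if (strand == "+") genomic_sense else rna_revcomp(genomic_sense))
    spacer_dna <- rna_to_dna(random_rna_seq(cfg$spacer))
    chrom_seqs[[chrom]] <- c(chrom_seqs[[chrom]], spacer_dna, chunk)

    # transcript-to-gene-sense coordinates (insert intron after exon A)
    tx2sense <- function(t) ifelse(t < exon_a_len, t, t + cfg$intron_len)
    sense2genomic <- function(sp) {
      if (strand == "+") g0 + sp else g0 + gene_len - 1L - sp
    }
    exons <- if (strand == "+") {
      tibble::tibble(start = c(g0, g0 + exon_a_len + cfg$intron_len),
                     end = c(g0 + exon_a_len, g0 + gene_len))
    } else {
      lenB <- gene_len - exon_a_len - cfg$intron_len
      tibble::tibble(start = c(g0, g0 + lenB + cfg$intron_len),
                     end = c(g0 + lenB, g0 + gene_len))
    }
    cds_tx <- c(cfg$utr5_len, cfg$utr5_len + cfg$cds_len)  # transcript span
    s_lo <- tx2sense(cds_tx[1]); s_hi <- tx2sense(cds_tx[2] - 1L)
    cds_genomic <- sort(c(sense2genomic(s_lo), sense2genomic(s_hi)))
    cds_genomic[2] <- cds_genomic[2] + 1L
    seg <- tibble::tibble(start = pmax(exons$start, cds_genomic[1]),
                          end = pmin(exons$end, cds_genomic[2]))
    seg <- seg[seg$end > seg$start, , drop = FALSE]
    models[[gene_ids[g]]] <- new_transcript_model(
      paste0(gene_ids[g], ".t1"), gene_ids[g], chrom, strand, exons, seg)

    if (!is.null(struct_tx)) {
      gsp <- sort(sense2genomic(tx2sense(c(struct_tx[1],
                                           struct_tx[2] - 1L))))
      gsp[2] <- gsp[2] + 1L
      sites_truth[[length(sites_truth) + 1L]] <- tibble::tibble(
        gene_id = gene_ids[g], chrom = chrom,
        struct_genomic_start = gsp[1], struct_genomic_end = gsp[2],
        struct_tx_start = struct_tx[1], struct_tx_end = struct_tx[2],
        peak_start = (gsp[1] %/% cfg$bin) * cfg$bin,
        peak_end = ((gsp[2] - 1L) %/% cfg$bin + 1L) * cfg$bin)
    }

    genes[[g]] <- tibble::tibble(
      gene_id = gene_ids[g], role = role, chrom = chrom, strand = strand,
      gene_start = g0, gene_end = g0 + gene_len,
      bound_region = dplyr::case_when(
        role %in% rg4_roles ~ "5'UTR",
        role == "cds_bound" ~ "CDS",
        role == "utr3_are" ~ "3'UTR",
        TRUE ~ NA_character_),
      rg4_subtype = subtype, are_class = are_class,
      te_planted = ifelse(gene_ids[g] %in% te_down_genes, "down",
                          "unchanged"),
      mrna_planted = dplyr::case_when(role == "mrna_up" ~ "up",
                                      role == "mrna_down" ~ "down",
                                      TRUE ~ "unchanged"))
  }
  genes <- dplyr::bind_rows(genes)
  genes$stringent <- genes$te_planted == "down" &
    genes$mrna_planted == "unchanged"
  sites_truth <- dplyr::bind_rows(sites_truth)
  if (nrow(sites_truth) == 0L) {
    sites_truth <- tibble::tibble(
      gene_id = character(), chrom = character(),
      struct_genomic_start = integer(), struct_genomic_end = integer(),
      struct_tx_start = integer(), struct_tx_end = integer(),
      peak_start = integer(), peak_end = integer())
  }
  genome <- vapply(chrom_seqs, paste, "", collapse = "")

  # background cleanup: the only structure hits anywhere in the genome
  # (either strand) must be the planted motif spans
  motif_genes <- genes$gene_id[!is.na(genes$rg4_subtype) |
                                 !is.na(genes$are_class)]
  for (ch in names(genome)) {
    prot <- sites_truth[sites_truth$chrom == ch &
                          sites_truth$gene_id %in% motif_genes,
                        c("struct_genomic_start", "struct_genomic_end")]
    names(prot) <- c("start", "end")
    genome[[ch]] <- clean_chromosome(genome[[ch]], prot)
  }

  # ---- CLIP coverage -------------------------------------------------------
  mu <- cfg$ztnb_r * (1 - cfg$ztnb_p) / cfg$ztnb_p
  make_track <- function() {
    dplyr::bind_rows(lapply(names(genome), function(ch) {
      n_bins <- nchar(genome[[ch]]) %/% cfg$bin
      counts <- stats::rnbinom(n_bins, size = cfg$ztnb_r, prob = cfg$ztnb_p)
      pk <- sites_truth[sites_truth$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(pk))) {
        b0 <- pk$peak_start[i] %/% cfg$bin + 1L
        b1 <- pk$peak_end[i] %/% cfg$bin
        counts[b0:b1] <- round(cfg$enrichment * mu) +
          stats::rnbinom(b1 - b0 + 1L, size = cfg$ztnb_r, prob = cfg$ztnb_p)
      }
      tibble::tibble(chrom = ch,
                     start = (seq_len(n_bins) - 1L) * cfg$bin,
                     end = seq_len(n_bins) * cfg$bin,
                     value = as.numeric(counts))
    }))
  }
  clip_rep1 <- make_track()
  clip_rep2 <- make_track()

  # ---- FPKM table ----------------------------------------------------------
  n <- nrow(genes)
  base_total <- stats::rlnorm(n, cfg$fpkm_meanlog, cfg$fpkm_sdlog)
  te_base <- stats::rlnorm(n, 0, 0.2)
  mrna_fc <- ifelse(genes$mrna_planted == "up", cfg$mrna_up_fc,
                    ifelse(genes$mrna_planted == "down", cfg$mrna_down_fc, 1))
  te_fc <- ifelse(genes$te_planted == "down", cfg$delta_te_down, 1)
  noise <- function() exp(rnorm(n, 0, cfg$sigma_rep))
  fpkm <- tibble::tibble(gene_id = genes$gene_id)
  for (rep in c("1", "2")) {
    fpkm[[paste0("fpkm_total_ctrl_", rep)]] <- base_total * noise()
    fpkm[[paste0("fpkm_polysome_ctrl_", rep)]] <- base_total * te_base *
      noise()
    fpkm[[paste0("fpkm_total_ko_", rep)]] <- base_total * mrna_fc * noise()
    fpkm[[paste0("fpkm_polysome_ko_", rep)]] <- base_total * mrna_fc *
      te_base * te_fc * noise()
  }

  truth <- list(genes = genes, sites = sites_truth)
  out <- list(genome = genome, models = models, clip_rep1 = clip_rep1,
              clip_rep2 = clip_rep2, fpkm = fpkm, truth = truth,
              config = cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genome, file.path(out_dir, "genome.fa"))
    write_gtf(models, file.path(out_dir, "annotation.gtf"))
    write_bedgraph(clip_rep1, file.path(out_dir, "clip_rep1.bedGraph"))
    write_bedgraph(clip_rep2, file.path(out_dir, "clip_rep2.bedGraph"))
    readr::write_tsv(fpkm, file.path(out_dir, "fpkm.tsv"))
    jsonlite::write_json(
      list(genes = genes, sites = sites_truth,
           config = cfg[setdiff(names(cfg), "")]),
      file.path(out_dir, "ground_truth.json"),
      dataframe = "columns", auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Deterministic 10-gene worked-example dataset
#'
#' A miniature cohort used in documentation and golden-file tests: one
#' gene with a canonical 5'UTR rG4, one with a bulge rG4, one with a
#' two-quartet rG4, one CDS-bound gene, one with a 3'UTR class-2 ARE and
#' five unbound controls. All planted TE-down genes use the default 0.4
#' TE ratio.
#'
#' @param out_dir Optional output directory (files as in
#'   [generate_synthetic_data()]).
#' @return The generated dataset list.
#' @export
worked_example_fixture <- function(out_dir = NULL) {
  cfg <- synthetic_config(
    seed = 42L, n_genes = 10L, genes_per_chrom = 5L,
    n_utr5_canonical = 1L, n_utr5_bulge = 1L, n_utr5_two_quartet = 1L,
    n_cds = 1L, n_utr3_are = 1L, n_mrna_up = 0L, n_mrna_down = 0L)
  generate_synthetic_data(cfg, out_dir)
}
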