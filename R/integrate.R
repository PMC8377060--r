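# Integration of binding sites with expression categories: per-gene
# records, figure-style tallies, KDE summaries, divergence classification
# and folding-energy comparisons.

mrna_regions <- c("5'UTR", "CDS", "3'UTR", "intron")

#' Build integrated per-gene records
#'
#' Joins region-annotated shared binding sites with categorised
#' expression records. A gene is `bound` when at least one shared site
#' lies on its representative transcript.
#'
#' @param sites Region-annotated site tibble from [assign_region()]
#'   (shared sites).
#' @param te_records Categorised expression tibble from
#'   [categorize_changes()].
#' @return Tibble with `gene_id`, `bound`, per-region logical columns
#'   `bound_5utr`, `bound_cds`, `bound_3utr`, `bound_intron`,
#'   `n_sites`, `te_category`, `mrna_category`, `log2_delta_te`,
#'   `log2_delta_mrna`, `expressed`, `consistent_trend`.
#' @export
integrate_records <- function(sites, te_records) {
  flag <- function(gene, region) {
    gene %in% sites$gene_id[!is.na(sites$gene_id) & sites$region == region]
  }
  out <- tibble::tibble(
    gene_id = te_records$gene_id,
    bound_5utr = flag(te_records$gene_id, "5'UTR"),
    bound_cds = flag(te_records$gene_id, "CDS"),
    bound_3utr = flag(te_records$gene_id, "3'UTR"),
    bound_intron = flag(te_records$gene_id, "intron"))
  out$bound <- out$bound_5utr | out$bound_cds | out$bound_3utr |
    out$bound_intron
  tab <- table(sites$gene_id[!is.na(sites$gene_id)])
  out$n_sites <- as.integer(tab[out$gene_id])
  out$n_sites[is.na(out$n_sites)] <- 0L
  dplyr::bind_cols(out,
                   te_records[, c("te_category", "mrna_category",
                                  "log2_delta_te", "log2_delta_mrna",
                                  "expressed", "consistent_trend")])
}

region_flag_col <- function(region) {
  c("5'UTR" = "bound_5utr", CDS = "bound_cds", "3'UTR" = "bound_3utr",
    intron = "bound_intron")[[region]]
}

#' Tally expression categories by bound region
#'
#' For every mRNA region, counts expressed genes bound in that region
#' (and, separately, bound *only* in that region) per TE and per mRNA
#' category.
#'
#' @param records Integrated records from [integrate_records()].
#' @return Tibble with `region`, `scope` (`any`/`only`), `category_type`
#'   (`te`/`mrna`), `up`, `down`, `unchanged`, `n_genes`.
#' @export
tally_by_region_and_category <- function(records) {
  recs <- records[records$expressed %in% TRUE, , drop = FALSE]
  flags <- as.matrix(recs[, vapply(mrna_regions, region_flag_col, "")])
  rows <- list()
  for (r in seq_along(mrna_regions)) {
    for (scope in c("any", "only")) {
      in_scope <- if (scope == "any") flags[, r]
      else flags[, r] & rowSums(flags) == 1L
      for (ct in c("te", "mrna")) {
        cats <- recs[[paste0(ct, "_category")]][in_scope]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          region = mrna_regions[r], scope = scope, category_type = ct,
          up = sum(cats == "up", na.rm = TRUE),
          down = sum(cats == "down", na.rm = TRUE),
          unchanged = sum(cats == "unchanged", na.rm = TRUE),
          n_genes = sum(in_scope))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Tally rG4 subtypes of binding sites split by host-gene category
#'
#' Classifies the sense sequence of every shared binding site (one best
#' subtype per site) and counts subtypes within TE-up and TE-down genes
#' bound in a given region. Counts are per site, not per gene.
#'
#' @param sites Region-annotated sites with `gene_id` and `region`.
#' @param site_sequences Character vector of site sense sequences,
#'   parallel to `sites` rows.
#' @param records Integrated records from [integrate_records()].
#' @param region Region whose bound genes are tallied.
#' @param category_type `"te"` or `"mrna"`.
#' @return Tibble with `category`, `subtype`, `n_sites`.
#' @export
tally_site_subtypes <- function(sites, site_sequences, records,
                                region = "5'UTR",
                                category_type = c("te", "mrna")) {
  category_type <- match.arg(category_type)
  stopifnot(length(site_sequences) == nrow(sites))
  cat_col <- paste0(category_type, "_category")
  cats <- setNames(records[[cat_col]], records$gene_id)
  keep <- which(!is.na(sites$gene_id) & sites$region == region)
  rows <- lapply(keep, function(i) {
    g <- sites$gene_id[i]
    if (is.na(cats[g]) || !cats[g] %in% c("up", "down")) return(NULL)
    tibble::tibble(category = unname(cats[g]),
                   subtype = classify_region_sequence(site_sequences[i]))
  })
  hits <- dplyr::bind_rows(rows)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(category = character(), subtype = character(),
                          n_sites = integer()))
  }
  dplyr::count(hits, .data$category, .data$subtype, name = "n_sites")
}

#' Kernel density estimates of expression shifts per exclusive region
#'
#' Gaussian KDE (Scott's-rule bandwidth) of `log2_delta_te` or
#' `log2_delta_mrna` for genes bound only in each region, evaluated on a
#' common grid.
#'
#' @param records Integrated records.
#' @param value `"log2_delta_te"` or `"log2_delta_mrna"`.
#' @param min_genes Minimum class size; smaller classes are skipped with
#'   a note in the result.
#' @param n_grid Grid resolution.
#' @return List with `grid`, per-region `density` tibble (columns
#'   `region`, `x`, `y`), `skipped` (regions with too few genes) and
#'   `degenerate` (regions whose values are all identical).
#' @export
delta_density_summary <- function(records, value = "log2_delta_te",
                                  min_genes = 5L, n_grid = 512L) {
  recs <- records[records$expressed %in% TRUE, , drop = FALSE]
  flags <- as.matrix(recs[, vapply(mrna_regions, region_flag_col, "")])
  only <- flags & rowSums(flags) == 1L
  dens <- list()
  skipped <- character()
  degenerate <- character()
  for (r in seq_along(mrna_regions)) {
    x <- recs[[value]][only[, r]]
    x <- x[!is.na(x)]
    if (length(x) < min_genes) {
      skipped <- c(skipped, mrna_regions[r])
      next
    }
    if (length(unique(x)) == 1L) {
      degenerate <- c(degenerate, mrna_regions[r])
      next
    }
    d <- density(x, bw = stats::bw.nrd(x), n = n_grid)
    dens[[length(dens) + 1L]] <- tibble::tibble(
      region = mrna_regions[r], x = d$x, y = d$y)
  }
  list(density = dplyr::bind_rows(dens), skipped = skipped,
       degenerate = degenerate)
}

#' Classify genes into the nine TE-by-mRNA divergence cells
#'
#' Each expressed gene is placed by comparing |log2 delta TE| and
#' |log2 delta FPKM-total| against the threshold (strictly greater than
#' `threshold` counts as changed, so the "constant" band is closed).
#'
#' @param records Integrated records.
#' @param threshold Band half-width on log2 scale (0.585 = log2(1.5)).
#' @return `records` subset to expressed genes with defined ratios, plus
#'   `te_cell` and `mrna_cell` (`down`/`constant`/`up`) and `cell`
#'   (their combination).
#' @export
divergence_classes <- function(records, threshold = 0.585) {
  recs <- records[records$expressed %in% TRUE &
                    !is.na(records$log2_delta_te) &
                    !is.na(records$log2_delta_mrna), , drop = FALSE]
  cell_of <- function(v) {
    dplyr::case_when(v > threshold ~ "up",
                     v < -threshold ~ "down",
                     TRUE ~ "constant")
  }
  recs$te_cell <- cell_of(recs$log2_delta_te)
  recs$mrna_cell <- cell_of(recs$log2_delta_mrna)
  recs$cell <- paste0("te_", recs$te_cell, ":mrna_", recs$mrna_cell)
  recs
}

#' Folding-energy comparisons of focal gene sets against background
#'
#' For each focal set (e.g. TE-up and TE-down genes with 5'UTR binding)
#' compares length-normalised `dG_rG4` and `dG_dsRNA` against the
#' background genes by one-tailed Mann-Whitney test.
#'
#' @param energies Tibble from [fold_energies()] rows with a `gene_id`
#'   column (one window per gene).
#' @param focal_sets Named list of gene-id character vectors.
#' @param background_genes Character vector of background gene ids.
#' @param alternative Tail direction passed to [compare_energy_sets()];
#'   the default asks whether focal windows are more stable (lower
#'   dsRNA MFE, larger rG4 gap).
#' @return Tibble with one row per (focal set, statistic): columns from
#'   [compare_energy_sets()] plus `focal_set` and `statistic`.
#' @export
energy_report <- function(energies, focal_sets, background_genes,
                          alternative = NULL) {
  stopifnot("gene_id" %in% names(energies))
  bg <- energies[energies$gene_id %in% background_genes, , drop = FALSE]
  rows <- list()
  for (nm in names(focal_sets)) {
    foc <- energies[energies$gene_id %in% focal_sets[[nm]], , drop = FALSE]
    if (nrow(foc) == 0L) next
    for (stat in c("dG_rG4_norm", "dG_dsRNA_norm")) {
      # larger dG_rG4 gap = more stable G4; lower dsRNA MFE = more stable
      alt <- if (is.null(alternative)) {
        if (stat == "dG_rG4_norm") "greater" else "less"
      } else alternative
      cmp <- compare_energy_sets(foc[[stat]], bg[[stat]], alternative = alt)
      cmp$focal_set <- nm
      cmp$statistic <- stat
      rows[[length(rows) + 1L]] <- cmp
    }
  }
  dplyr::bind_rows(rows)
}
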