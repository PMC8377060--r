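# Translational efficiency (TE) from polysome-profiling FPKM tables.
#
# TE = FPKM-polysome / FPKM-total per condition; the KO/Ctrl TE ratio
# (delta TE) is categorised with the inclusive 1.5-fold thresholds
# (up: >= 1.5, down: <= 0.66). Only genes whose TE moves in the same
# direction in both replicates are carried forward, using their
# replicate-averaged FPKM values; for integration with binding data
# genes additionally need averaged FPKM-total > 1 in either condition.

#' Compute per-replicate and averaged translational efficiency
#'
#' @param table Tibble from [read_fpkm_table()]: `gene_id` plus
#'   `fpkm_<fraction>_<condition>_<rep>` columns.
#' @return Tibble with per-replicate TEs, averaged FPKMs, averaged-value
#'   TE ratio `delta_te` (= TE_KO / TE_Ctrl), `log2_delta_te`,
#'   `log2_delta_mrna` (averaged FPKM-total KO/Ctrl) and `te_defined`
#'   (FALSE where any required denominator is zero; such genes are kept
#'   in the table, flagged, and excluded from ratio columns as `NA`).
#' @export
compute_te <- function(table) {
  missing <- setdiff(c("gene_id", fpkm_columns()), names(table))
  if (length(missing)) {
    stop("FPKM table is missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- tibble::tibble(gene_id = table$gene_id)
  for (cond in c("ctrl", "ko")) {
    for (rep in c("1", "2")) {
      tot <- table[[paste("fpkm_total", cond, rep, sep = "_")]]
      pol <- table[[paste("fpkm_polysome", cond, rep, sep = "_")]]
      out[[paste0("te_", cond, "_", rep)]] <-
        ifelse(tot > 0, pol / tot, NA_real_)
    }
    out[[paste0("fpkm_total_", cond)]] <-
      (table[[paste0("fpkm_total_", cond, "_1")]] +
         table[[paste0("fpkm_total_", cond, "_2")]]) / 2
    out[[paste0("fpkm_polysome_", cond)]] <-
      (table[[paste0("fpkm_polysome_", cond, "_1")]] +
         table[[paste0("fpkm_polysome_", cond, "_2")]]) / 2
  }
  out$te_ctrl <- ifelse(out$fpkm_total_ctrl > 0,
                        out$fpkm_polysome_ctrl / out$fpkm_total_ctrl,
                        NA_real_)
  out$te_ko <- ifelse(out$fpkm_total_ko > 0,
                      out$fpkm_polysome_ko / out$fpkm_total_ko, NA_real_)
  out$te_defined <- stats::complete.cases(
    out[, c("te_ctrl_1", "te_ctrl_2", "te_ko_1", "te_ko_2",
            "te_ctrl", "te_ko")]) & out$te_ctrl > 0
  out$delta_te <- ifelse(out$te_defined, out$te_ko / out$te_ctrl, NA_real_)
  out$log2_delta_te <- log2(out$delta_te)
  out$log2_delta_mrna <- ifelse(
    out$fpkm_total_ctrl > 0 & out$fpkm_total_ko > 0,
    log2(out$fpkm_total_ko / out$fpkm_total_ctrl), NA_real_)
  out
}

#' Flag genes whose TE change is replicate-consistent
#'
#' Consistent means the per-replicate TE ratios move strictly in the same
#' direction (both up or both down); a replicate ratio of exactly 1 is
#' direction-less and therefore inconsistent.
#'
#' @param records Tibble from [compute_te()].
#' @return `records` with a logical `consistent_trend` column (`FALSE`
#'   for genes with undefined TEs).
#' @export
consistency_filter <- function(records) {
  s1 <- sign(log(records$te_ko_1 / records$te_ctrl_1))
  s2 <- sign(log(records$te_ko_2 / records$te_ctrl_2))
  records$consistent_trend <- !is.na(s1) & !is.na(s2) &
    s1 == s2 & s1 != 0
  records$consistent_trend[!records$te_defined] <- FALSE
  records
}

#' Categorise TE and mRNA-abundance changes
#'
#' Categories use the averaged-value ratios with inclusive thresholds:
#' `up` for fold change >= `up`, `down` for <= `down`, else `unchanged`.
#' Categories are only assigned to replicate-consistent genes (TE) and
#' genes with defined ratios (mRNA); others get `NA`. The `expressed`
#' flag marks genes with averaged FPKM-total > `express_min` in either
#' condition, the filter used for binding-integration analyses.
#'
#' @param records Tibble from [consistency_filter()].
#' @param up,down Fold-change thresholds.
#' @param express_min Expressed-gene FPKM-total cutoff.
#' @return `records` with `te_category`, `mrna_category`, `expressed`.
#' @export
categorize_changes <- function(records, up = 1.5, down = 0.66,
                               express_min = 1) {
  if (!"consistent_trend" %in% names(records)) {
    records <- consistency_filter(records)
  }
  cat_of <- function(fc) {
    dplyr::case_when(is.na(fc) ~ NA_character_,
                     fc >= up ~ "up",
                     fc <= down ~ "down",
                     TRUE ~ "unchanged")
  }
  records$te_category <- cat_of(records$delta_te)
  records$te_category[!records$consistent_trend] <- NA_character_
  records$mrna_category <- cat_of(2^records$log2_delta_mrna)
  records$expressed <- records$fpkm_total_ctrl > express_min |
    records$fpkm_total_ko > express_min
  records
}

#' Stringent TE-down gene subset
#'
#' Genes with essentially constant mRNA (|log2 delta FPKM-total| <=
#' `mrna_band`) whose TE drops more than two-fold
#' (log2 delta TE strictly below `te_cut`).
#'
#' @param records Categorised records from [categorize_changes()].
#' @param te_cut Strict upper bound on log2 delta TE.
#' @param mrna_band Half-width of the constant-mRNA band on log2 scale.
#' @return Character vector of gene ids.
#' @export
stringent_te_down <- function(records, te_cut = -1, mrna_band = 0.585) {
  keep <- !is.na(records$log2_delta_te) & !is.na(records$log2_delta_mrna) &
    records$consistent_trend &
    records$log2_delta_te < te_cut &
    abs(records$log2_delta_mrna) <= mrna_band
  records$gene_id[keep]
}
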