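# CLIP binding-site calling from binned coverage.
#
# Counts per 100-nt bin are modelled with a single zero-truncated
# negative binomial (ZTNB) fitted to all nonzero bins; each bin gets an
# upper-tail P value under the fitted model and bins below the
# significance threshold become binding sites (adjacent significant bins
# merged). Replicate agreement is assessed by site overlap and by the
# Pearson correlation of coverage in 10-kbp bins.

# ---- ZTNB distribution -----------------------------------------------------

#' Zero-truncated negative binomial probability mass
#'
#' @param k Positive integer count(s).
#' @param size,prob Negative binomial parameters (`size` = dispersion r,
#'   `prob` = success probability p).
#' @return P(X = k | X >= 1).
#' @export
dztnb <- function(k, size, prob) {
  p0 <- dnbinom(0, size = size, prob = prob)
  out <- dnbinom(k, size = size, prob = prob) / (1 - p0)
  out[k < 1] <- 0
  out
}

#' Zero-truncated negative binomial upper tail
#'
#' @param k Positive integer count(s).
#' @param size,prob Negative binomial parameters.
#' @return P(X >= k | X >= 1), 1 for k <= 1.
#' @export
pztnb_upper <- function(k, size, prob) {
  p0 <- dnbinom(0, size = size, prob = prob)
  out <- pnbinom(pmax(k, 1) - 1, size = size, prob = prob,
                 lower.tail = FALSE) / (1 - p0)
  pmin(out, 1)
}

#' Draw from a zero-truncated negative binomial
#'
#' Inverse-CDF sampling restricted to the positive support.
#'
#' @param n Number of draws.
#' @param size,prob Negative binomial parameters.
#' @return Integer vector of positive counts.
#' @export
rztnb <- function(n, size, prob) {
  p0 <- dnbinom(0, size = size, prob = prob)
  u <- runif(n, min = p0, max = 1)
  pmax(1L, as.integer(qnbinom(u, size = size, prob = prob)))
}

#' Fit a zero-truncated negative binomial by maximum likelihood
#'
#' Numeric optimisation on (log r, logit p), initialised by method of
#' moments on the truncated sample. Near-equidispersed degenerate input
#' (all counts equal, or variance not above the mean) falls back to a
#' zero-truncated Poisson limit with a warning.
#'
#' @param counts Positive integer counts (nonzero bins).
#' @param min_bins Minimum number of counts required for a fit.
#' @return List of class `ztnb_model` with `family` (`"ztnb"` or
#'   `"ztpois"`), parameters, log-likelihood and `converged` flag.
#' @export
fit_ztnb <- function(counts, min_bins = 30L) {
  counts <- as.integer(counts)
  if (any(counts < 1L)) stop("fit_ztnb() expects positive counts")
  if (length(counts) < min_bins) {
    stop("need at least ", min_bins, " nonzero bins, got ", length(counts))
  }
  m <- mean(counts)
  v <- stats::var(counts)

  if (v <= m || length(unique(counts)) == 1L) {
    warning("counts are not overdispersed; falling back to a ",
            "zero-truncated Poisson limit")
    # solve m = lambda / (1 - exp(-lambda))
    lam <- if (m <= 1) 1e-6 else {
      uniroot(function(l) l / (1 - exp(-l)) - m,
              interval = c(1e-8, max(m * 2, 2)))$root
    }
    return(structure(list(family = "ztpois", lambda = lam,
                          loglik = NA_real_, converged = TRUE),
                     class = "ztnb_model"))
  }

  # method-of-moments start, ignoring the truncation
  p0 <- min(max(m / v, 1e-4), 1 - 1e-4)
  r0 <- max(m * p0 / (1 - p0), 1e-3)
  nll <- function(theta) {
    r <- exp(theta[1])
    p <- stats::plogis(theta[2])
    # extreme exploratory steps can overflow dnbinom; treat as infeasible
    ll <- suppressWarnings(
      sum(dnbinom(counts, size = r, prob = p, log = TRUE)) -
        length(counts) * log1p(-p^r))
    if (!is.finite(ll)) 1e10 else -ll
  }
  fit <- optim(c(log(r0), stats::qlogis(p0)), nll, method = "BFGS",
               control = list(maxit = 500))
  structure(list(family = "ztnb",
                 size = exp(fit$par[1]), prob = stats::plogis(fit$par[2]),
                 loglik = -fit$value,
                 converged = fit$convergence == 0),
            class = "ztnb_model")
}

#' @export
print.ztnb_model <- function(x, ...) {
  if (x$family == "ztnb") {
    cat(sprintf("<ztnb_model> r = %.4g, p = %.4g (loglik %.2f, %s)\n",
                x$size, x$prob, x$loglik,
                if (x$converged) "converged" else "NOT converged"))
  } else {
    cat(sprintf("<ztnb_model> zero-truncated Poisson limit, lambda = %.4g\n",
                x$lambda))
  }
  invisible(x)
}

ztnb_upper_tail <- function(k, model) {
  if (model$family == "ztnb") {
    pztnb_upper(k, model$size, model$prob)
  } else {
    p0 <- stats::dpois(0, model$lambda)
    pmin(stats::ppois(pmax(k, 1) - 1, model$lambda,
                      lower.tail = FALSE) / (1 - p0), 1)
  }
}

# ---- binning ---------------------------------------------------------------

#' Bin a bedGraph coverage track into read counts
#'
#' The count of a bin is the coverage area (value x bases) inside the bin
#' divided by `read_length`, rounded to an integer. With the default
#' `read_length = bin` a track holding constant per-bin read counts
#' round-trips exactly.
#'
#' @param track Tibble from [read_bedgraph()].
#' @param bin Bin size in nt.
#' @param read_length Divisor converting coverage area to read counts.
#' @return Tibble with `chrom`, `start`, `end`, `count` for every bin up
#'   to the last covered position of each chromosome.
#' @export
bin_coverage <- function(track, bin = 100L, read_length = bin) {
  if (any(track$value < 0)) stop("negative coverage values")
  if (bin <= 0L) stop("bin size must be positive")
  out <- lapply(split(track, track$chrom), function(tr) {
    n_bins <- ceiling(max(tr$end) / bin)
    area <- numeric(n_bins)
    for (i in seq_len(nrow(tr))) {
      b0 <- tr$start[i] %/% bin
      b1 <- (tr$end[i] - 1L) %/% bin
      for (b in b0:b1) {
        ov <- overlap_length(tr$start[i], tr$end[i], b * bin, (b + 1L) * bin)
        area[b + 1L] <- area[b + 1L] + tr$value[i] * ov
      }
    }
    tibble::tibble(chrom = tr$chrom[1],
                   start = (seq_len(n_bins) - 1L) * bin,
                   end = seq_len(n_bins) * bin,
                   count = as.integer(round(area / read_length)))
  })
  dplyr::bind_rows(out)
}

#' Bin read intervals by start coordinate
#'
#' Each read is assigned to the bin containing its start.
#'
#' @param reads Tibble with `chrom`, `start`, `end`.
#' @param bin Bin size in nt.
#' @return Tibble with `chrom`, `start`, `end`, `count`.
#' @export
bin_reads <- function(reads, bin = 100L) {
  out <- lapply(split(reads, reads$chrom), function(rd) {
    n_bins <- ceiling(max(rd$end) / bin)
    idx <- rd$start %/% bin + 1L
    counts <- tabulate(idx, nbins = n_bins)
    tibble::tibble(chrom = rd$chrom[1],
                   start = (seq_len(n_bins) - 1L) * bin,
                   end = seq_len(n_bins) * bin,
                   count = as.integer(counts))
  })
  dplyr::bind_rows(out)
}

# ---- peak calling ----------------------------------------------------------

#' Call binding sites from binned counts under a fitted ZTNB model
#'
#' Every nonzero bin gets the upper-tail probability of a count at least
#' as large; bins with `P < alpha` are significant and adjacent
#' significant bins are merged into one site keeping the minimum P.
#'
#' @param bins Tibble from [bin_coverage()] or [bin_reads()].
#' @param model A `ztnb_model` from [fit_ztnb()].
#' @param alpha Significance threshold.
#' @param adjust Optionally `"BH"` for Benjamini-Hochberg adjustment of
#'   the nonzero-bin P values before thresholding (off by default).
#' @return Tibble of sites: `chrom`, `start`, `end`, `count` (max bin
#'   count), `p_value` (min bin P), `n_bins`.
#' @export
call_peaks <- function(bins, model, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  nz <- bins[bins$count > 0L, , drop = FALSE]
  if (nrow(nz) == 0L || alpha <= 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), count = integer(),
                          p_value = numeric(), n_bins = integer()))
  }
  p <- ztnb_upper_tail(nz$count, model)
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  sig <- nz[p < alpha, , drop = FALSE]
  sig$p_value <- p[p < alpha]
  if (nrow(sig) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), count = integer(),
                          p_value = numeric(), n_bins = integer()))
  }
  sig <- dplyr::arrange(sig, .data$chrom, .data$start)
  grp <- cumsum(c(1L, as.integer(
    sig$chrom[-1L] != sig$chrom[-nrow(sig)] |
      sig$start[-1L] != sig$end[-nrow(sig)])))
  dplyr::bind_rows(lapply(split(sig, grp), function(g) {
    tibble::tibble(chrom = g$chrom[1], start = min(g$start),
                   end = max(g$end), count = max(g$count),
                   p_value = min(g$p_value), n_bins = nrow(g))
  }))
}

#' Intersect binding sites between replicates
#'
#' A site is shared when it overlaps (>= 1 bp) a site of the other
#' replicate; shared loci are reported as the union of the overlapping
#' replicate spans. Also reports the rep1-anchored shared count.
#'
#' @param sites_rep1,sites_rep2 Site tables from [call_peaks()].
#' @return List with `shared` (union-merged tibble with min `p_value`
#'   across contributing sites), `n_rep1_shared`, `n_rep2_shared`,
#'   `n_union_loci`, and the per-replicate overlap proportions
#'   `prop_rep1`, `prop_rep2`.
#' @export
intersect_replicates <- function(sites_rep1, sites_rep2) {
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), p_value = numeric())
  if (nrow(sites_rep1) == 0L || nrow(sites_rep2) == 0L) {
    return(list(shared = empty, n_rep1_shared = 0L, n_rep2_shared = 0L,
                n_union_loci = 0L, prop_rep1 = 0, prop_rep2 = 0))
  }
  pairs <- overlap_pairs(sites_rep1, sites_rep2)
  if (nrow(pairs) == 0L) {
    return(list(shared = empty, n_rep1_shared = 0L, n_rep2_shared = 0L,
                n_union_loci = 0L, prop_rep1 = 0, prop_rep2 = 0))
  }
  both <- dplyr::bind_rows(
    dplyr::mutate(sites_rep1[unique(pairs$i), c("chrom", "start", "end")],
                  p_value = sites_rep1$p_value[unique(pairs$i)]),
    dplyr::mutate(sites_rep2[unique(pairs$j), c("chrom", "start", "end")],
                  p_value = sites_rep2$p_value[unique(pairs$j)]))
  merged <- merge_intervals(both, gap = -1L)
  # carry the minimum P of contributing replicate sites per merged locus
  mp <- overlap_pairs(merged, both)
  pv <- vapply(split(both$p_value[mp$j], mp$i), min, numeric(1))
  merged$p_value <- NA_real_
  merged$p_value[as.integer(names(pv))] <- pv
  list(shared = merged,
       n_rep1_shared = length(unique(pairs$i)),
       n_rep2_shared = length(unique(pairs$j)),
       n_union_loci = nrow(merged),
       prop_rep1 = length(unique(pairs$i)) / nrow(sites_rep1),
       prop_rep2 = length(unique(pairs$j)) / nrow(sites_rep2))
}

#' Pearson correlation of replicate coverage in large bins
#'
#' Quality-control statistic: coverage of each replicate summed in
#' `bin`-sized windows (default 10 kbp) and correlated.
#'
#' @param track1,track2 Coverage tibbles from [read_bedgraph()].
#' @param bin Bin size in nt.
#' @return Pearson correlation coefficient.
#' @export
replicate_coverage_cor <- function(track1, track2, bin = 10000L) {
  b1 <- bin_coverage(track1, bin = bin, read_length = 1L)
  b2 <- bin_coverage(track2, bin = bin, read_length = 1L)
  joint <- dplyr::full_join(b1, b2, by = c("chrom", "start", "end"),
                            suffix = c("_1", "_2"))
  joint[is.na(joint)] <- 0L
  stats::cor(joint$count_1, joint$count_2, method = "pearson")
}

# ---- region annotation -----------------------------------------------------

#' Pick the representative (longest mature) transcript per gene
#'
#' @param models Named list of `transcript_model` objects.
#' @return Named list, one model per gene id.
#' @export
representative_transcripts <- function(models) {
  genes <- split(models, vapply(models, function(m) m$gene_id, ""))
  lapply(genes, function(ms) {
    ms[[which.max(vapply(ms, function(m) m$tx_length, 0L))]]
  })
}

#' Assign binding sites to transcript regions
#'
#' Each site is labelled by majority overlap with the genomic footprint
#' of the representative transcript per gene; ties break in the order
#' 5'UTR > CDS > 3'UTR > intron > ncRNA. Sites overlapping no transcript
#' get label `other`.
#'
#' @param sites Site tibble (`chrom`, `start`, `end`, ...).
#' @param models Named list of `transcript_model` objects (all isoforms;
#'   representatives are chosen internally).
#' @return `sites` with added `region` and `gene_id` columns.
#' @export
assign_region <- function(sites, models) {
  reps <- representative_transcripts(models)
  footprint <- dplyr::bind_rows(lapply(reps, function(m) {
    dplyr::mutate(region_genomic_intervals(m), gene_id = m$gene_id)
  }))
  rank <- c("5'UTR" = 1, CDS = 2, "3'UTR" = 3, intron = 4, ncRNA = 5)
  sites$region <- "other"
  sites$gene_id <- NA_character_
  if (nrow(sites) == 0L || nrow(footprint) == 0L) return(sites)
  pairs <- overlap_pairs(sites, footprint)
  if (nrow(pairs) == 0L) return(sites)
  pairs$ov <- overlap_length(sites$start[pairs$i], sites$end[pairs$i],
                             footprint$start[pairs$j],
                             footprint$end[pairs$j])
  pairs$region <- footprint$region[pairs$j]
  pairs$gene_id <- footprint$gene_id[pairs$j]
  agg <- dplyr::summarise(
    dplyr::group_by(pairs, .data$i, .data$region, .data$gene_id),
    ov = sum(.data$ov), .groups = "drop")
  agg <- dplyr::arrange(agg, .data$i, dplyr::desc(.data$ov),
                        rank[.data$region])
  best <- agg[!duplicated(agg$i), , drop = FALSE]
  sites$region[best$i] <- best$region
  sites$gene_id[best$i] <- best$gene_id
  sites
}

#' Binding-site density per transcript region
#'
#' Sites per 1000 nt of region, with two denominators: the summed region
#' length over all representative transcripts and over bound ones only.
#'
#' @param sites Region-annotated sites from [assign_region()].
#' @param models Named list of `transcript_model` objects.
#' @return Tibble with `region`, `n_sites`, `total_length_all`,
#'   `density_all`, `total_length_bound`, `density_bound` (densities per
#'   1000 nt; `NA` where the denominator is zero).
#' @export
region_density <- function(sites, models) {
  reps <- representative_transcripts(models)
  lens <- dplyr::bind_rows(lapply(reps, function(m) {
    rl <- region_lengths(m)
    tibble::tibble(gene_id = m$gene_id, region = names(rl),
                   length = as.integer(rl))
  }))
  bound_genes <- unique(stats::na.omit(sites$gene_id))
  per_region <- dplyr::summarise(
    dplyr::group_by(lens, .data$region),
    total_length_all = sum(.data$length),
    total_length_bound = sum(.data$length[.data$gene_id %in% bound_genes]),
    .groups = "drop")
  counts <- table(factor(sites$region, levels = per_region$region))
  per_region$n_sites <- as.integer(counts[per_region$region])
  dplyr::mutate(
    per_region,
    density_all = ifelse(.data$total_length_all > 0,
                         1000 * .data$n_sites / .data$total_length_all,
                         NA_real_),
    density_bound = ifelse(.data$total_length_bound > 0,
                           1000 * .data$n_sites / .data$total_length_bound,
                           NA_real_))[, c("region", "n_sites",
                                          "total_length_all", "density_all",
                                          "total_length_bound",
                                          "density_bound")]
}
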