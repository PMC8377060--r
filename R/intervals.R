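#' Construct a genomic interval table
#'
#' Intervals are 0-based half-open `[start, end)` everywhere inside the
#' package; GTF/BED readers and writers convert at the boundary.
#'
#' @param chrom Character vector of sequence names.
#' @param start,end Integer vectors, `0 <= start < end`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unstranded); recycled.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 0L)) stop("interval start must be non-negative")
  if (any(start >= end)) stop("interval must satisfy start < end")
  if (!all(strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'")
  }
  tibble::tibble(chrom = as.character(chrom), start = start, end = end,
                 strand = as.character(strand))
}

#' Overlap length of two half-open intervals
#'
#' @param start1,end1,start2,end2 Interval bounds (vectorised).
#' @return Integer overlap in bases, 0 for disjoint intervals.
#' @export
overlap_length <- function(start1, end1, start2, end2) {
  pmax(0L, pmin(end1, end2) - pmax(start1, start2))
}

#' Merge intervals closer than a gap (bedtools-merge semantics)
#'
#' Intervals whose inter-interval gap is `<= gap` are unioned, per
#' `chrom`. A gap of 0 merges touching (book-ended) intervals.
#'
#' @param x Tibble with `chrom`, `start`, `end` (and optionally more
#'   columns, which are dropped).
#' @param gap Maximum gap (nt) between merged intervals.
#' @return Tibble of merged `chrom`, `start`, `end`, sorted.
#' @export
merge_intervals <- function(x, gap = 0L) {
  if (nrow(x) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  x <- dplyr::arrange(x, .data$chrom, .data$start, .data$end)
  out <- vector("list", nrow(x))
  n_out <- 0L
  cur <- NULL
  for (i in seq_len(nrow(x))) {
    row <- list(chrom = x$chrom[i], start = x$start[i], end = x$end[i])
    if (is.null(cur)) {
      cur <- row
    } else if (row$chrom == cur$chrom && row$start - cur$end <= gap) {
      cur$end <- max(cur$end, row$end)
    } else {
      n_out <- n_out + 1L
      out[[n_out]] <- cur
      cur <- row
    }
  }
  out[[n_out + 1L]] <- cur
  dplyr::bind_rows(out[seq_len(n_out + 1L)])
}

# IRanges-backed overlap join between two site tables; returns pairs of
# row indices (queryHits on a, subjectHits on b).
overlap_pairs <- function(a, b) {
  hits <- lapply(intersect(unique(a$chrom), unique(b$chrom)), function(ch) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    ra <- IRanges::IRanges(start = a$start[ia] + 1L, end = a$end[ia])
    rb <- IRanges::IRanges(start = b$start[ib] + 1L, end = b$end[ib])
    ov <- IRanges::findOverlaps(ra, rb)
    tibble::tibble(i = ia[S4Vectors::queryHits(ov)],
                   j = ib[S4Vectors::subjectHits(ov)])
  })
  dplyr::bind_rows(hits)
}
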