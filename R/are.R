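# AU-rich element (ARE) annotation.
#
# Three classes of conventional ARE patterns:
#   class1 : AUUUA pentamers in a U-rich context -- the W-flank patterns
#            WWUUUWW / WWWUUUWWW / WWWWUUUWWWW (W = A or U), plus a
#            dispersed detector (>= 2 non-overlapping AUUUA pentamers
#            spanning <= `dispersed_window` nt with U fraction >=
#            `dispersed_min_u` over the span)
#   class2 : two to five overlapping AUUUA pentamers, i.e. A(UUUA){2,5};
#            overlapping pentamers share the bridging A (period 4)
#   class3 : U-rich runs of more than five, i.e. >= 6, consecutive Us
#
# When one locus matches multiple categories the shorter hits are removed
# (longest kept); finally class-1 and class-3 hits within 5 nt of each
# other are merged into a single `merged` annotation. Class 2 is never
# merged.

are_w_patterns <- function() {
  c("[AU]{2}UUU[AU]{2}", "[AU]{3}UUU[AU]{3}", "[AU]{4}UUU[AU]{4}")
}

find_all_matches <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  tibble::tibble(start = as.integer(m) - 1L,
                 end = as.integer(m) - 1L + attr(m, "match.length"))
}

# dispersed AUUUA clusters: chains of non-overlapping pentamers where the
# chain's bounding span stays within `window` nt and is U-rich
dispersed_auua_hits <- function(seq, window, min_u) {
  pent <- find_all_matches(seq, "AUUUA")
  if (nrow(pent) < 2L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  # greedy non-overlapping selection, left to right
  keep <- integer()
  last_end <- -1L
  for (i in seq_len(nrow(pent))) {
    if (pent$start[i] >= last_end) {
      keep <- c(keep, i)
      last_end <- pent$end[i]
    }
  }
  pent <- pent[keep, , drop = FALSE]
  if (nrow(pent) < 2L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  hits <- list()
  i <- 1L
  while (i < nrow(pent)) {
    j <- i
    while (j + 1L <= nrow(pent) &&
           pent$end[j + 1L] - pent$start[i] <= window) {
      j <- j + 1L
    }
    if (j > i) {
      span <- substr(seq, pent$start[i] + 1L, pent$end[j])
      u_frac <- stringr::str_count(span, "U") / nchar(span)
      if (u_frac >= min_u) {
        hits[[length(hits) + 1L]] <- tibble::tibble(start = pent$start[i],
                                                    end = pent$end[j])
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  dplyr::bind_rows(hits)
}

#' Scan a sequence for AU-rich elements
#'
#' Runs the three class detectors, removes shorter multi-category
#' duplicates and merges nearby class-1/class-3 hits (see
#' [dedup_and_merge()]).
#'
#' @param seq RNA string.
#' @param id Sequence identifier carried into the result.
#' @param dispersed_window Maximum span (nt) of a dispersed-AUUUA cluster.
#' @param dispersed_min_u Minimum U fraction over a dispersed cluster.
#' @return Tibble with `seq_id`, `start`, `end`, `are_class` (one of
#'   `class1`, `class2`, `class3`, `merged`), `matched`, `constituents`.
#' @export
scan_are <- function(seq, id = "seq", dispersed_window = 30L,
                     dispersed_min_u = 0.5) {
  if (length(seq) != 1L) stop("scan_are() expects a single sequence")
  seq <- as_rna(seq)
  empty <- tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), are_class = character(),
                          matched = character(), constituents = character())
  if (nchar(seq) == 0L) return(empty)

  c1 <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(are_w_patterns(),
                            function(p) find_all_matches(seq, p))),
    dispersed_auua_hits(seq, dispersed_window, dispersed_min_u))
  c2 <- find_all_matches(seq, "A(?:UUUA){2,5}")
  c3 <- find_all_matches(seq, "U{6,}")

  hits <- dplyr::bind_rows(
    if (nrow(c1)) dplyr::mutate(c1, are_class = "class1"),
    if (nrow(c2)) dplyr::mutate(c2, are_class = "class2"),
    if (nrow(c3)) dplyr::mutate(c3, are_class = "class3"))
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  hits <- dplyr::arrange(hits, .data$start, .data$end)
  out <- dedup_and_merge(hits)
  out$seq_id <- id
  out$matched <- substr(rep(seq, nrow(out)), out$start + 1L, out$end)
  out[, c("seq_id", "start", "end", "are_class", "matched", "constituents")]
}

#' Remove shorter duplicate AREs and merge nearby class-1/class-3 hits
#'
#' Overlapping hits from multiple categories are reduced to the longest
#' (ties broken by class order); surviving class-1 and class-3 intervals
#' with an inter-interval gap of at most 5 nt become one `merged`
#' annotation. Class-2 hits are never merged.
#'
#' @param hits Tibble with `start`, `end`, `are_class`, sorted by span.
#' @param merge_gap Maximum gap (nt) for the class-1/class-3 merge.
#' @return Tibble with `start`, `end`, `are_class`, `constituents`.
#' @export
dedup_and_merge <- function(hits, merge_gap = 5L) {
  stopifnot(all(c("start", "end", "are_class") %in% names(hits)))
  if (nrow(hits) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          are_class = character(), constituents = character()))
  }
  # longest-first; ties prefer the more specific overlapping-pentamer
  # class (class2) over the context classes; drop hits overlapping a kept one
  pref <- match(hits$are_class, c("class2", "class1", "class3"))
  ord <- order(-(hits$end - hits$start), pref, hits$start)
  hits <- hits[ord, , drop = FALSE]
  kept <- hits[0, , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    if (nrow(kept) == 0L ||
        all(overlap_length(hits$start[i], hits$end[i],
                           kept$start, kept$end) == 0L)) {
      kept <- rbind(kept, hits[i, , drop = FALSE])
    }
  }
  kept <- kept[order(kept$start), , drop = FALSE]

  mergeable <- kept$are_class %in% c("class1", "class3")
  m13 <- kept[mergeable, , drop = FALSE]
  out <- kept[!mergeable, , drop = FALSE]
  out$constituents <- out$are_class
  if (nrow(m13) > 0L) {
    grp <- cumsum(c(1L, as.integer(
      m13$start[-1L] - m13$end[-nrow(m13)] > merge_gap)))
    merged <- dplyr::bind_rows(lapply(split(m13, grp), function(g) {
      tibble::tibble(
        start = min(g$start), end = max(g$end),
        are_class = if (nrow(g) > 1L) "merged" else g$are_class,
        constituents = paste(sort(unique(g$are_class)), collapse = "+"))
    }))
    out <- dplyr::bind_rows(out, merged)
  }
  dplyr::arrange(tibble::as_tibble(out), .data$start, .data$end)
}
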