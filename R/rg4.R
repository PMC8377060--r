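# rG4 subtype prediction.
#
# Subtypes, in decreasing predicted stability:
#   canonical   : >= 4 G-tracts of >= 3 Gs, loops 1-7 nt
#   long_loop   : 4 G-tracts of >= 3 Gs with exactly one elongated loop
#                 (lateral 8-12 nt, central 8-21 nt), remaining loops 1-7 nt
#   bulge       : three intact G>=3 tracts plus one tract interrupted by a
#                 1-7 nt non-G bulge (GGH(1-7)G | GH(1-7)GG, H in {A,U,C}),
#                 loops 1-9 nt; or two tracts each with a single 1-nt bulge
#                 (GGHG | GHGG), loops 1-9 nt
#   two_quartet : >= 4 G-tracts of >= 2 Gs, loops 1-9 nt
#
# Tract maximality: within a match, a G-tract may not be extensible by an
# adjacent G, so loops begin and end with a non-G (loops may still contain
# internal Gs). Scanning is leftmost and non-overlapping with lazy loop
# quantifiers; an overlapping lower-stability match at a locus already
# claimed by a higher-stability subtype is suppressed.

# loop of length in [lo, hi] whose first and last characters are non-G
loop_rx <- function(lo, hi) {
  stopifnot(lo >= 1, hi >= lo)
  one <- if (lo == 1) "[AUC]" else NULL
  multi <- if (hi >= 2) {
    sprintf("[AUC][ACGU]{%d,%d}?[AUC]", max(lo - 2L, 0L), hi - 2L)
  } else NULL
  paste0("(?:", paste(c(one, multi), collapse = "|"), ")")
}

#' rG4 subtype pattern specifications
#'
#' @return Tibble with `subtype`, `stability_rank` and the PCRE `pattern`
#'   used by [scan_rg4()], ordered from most to least stable.
#' @export
rg4_patterns <- function() {
  t3 <- "G{3,}"
  t2 <- "G{2,}"
  l17 <- loop_rx(1, 7)
  l19 <- loop_rx(1, 9)
  lat <- loop_rx(8, 12)   # elongated lateral loop
  cen <- loop_rx(8, 21)   # elongated central loop
  b17 <- "(?:GG[AUC]{1,7}G|G[AUC]{1,7}GG)"  # 1-7 nt bulge in one tract
  b1 <- "(?:GG[AUC]G|G[AUC]GG)"             # single 1-nt bulge

  canonical <- paste0("(?:", t3, l17, "){3,}", t3)

  ll_variants <- c(
    paste0(t3, lat, t3, l17, t3, l17, t3),
    paste0(t3, l17, t3, cen, t3, l17, t3),
    paste0(t3, l17, t3, l17, t3, lat, t3))
  long_loop <- paste0("(?:", paste(ll_variants, collapse = "|"), ")")

  tracts1 <- function(pos) {
    slots <- rep(t3, 4)
    slots[pos] <- b17
    paste0(slots[1], l19, slots[2], l19, slots[3], l19, slots[4])
  }
  tracts2 <- function(pos) {
    slots <- rep(t3, 4)
    slots[pos] <- b1
    paste0(slots[1], l19, slots[2], l19, slots[3], l19, slots[4])
  }
  pairs <- utils::combn(4, 2, simplify = FALSE)
  bulge <- paste0("(?:",
                  paste(c(vapply(1:4, tracts1, ""),
                          vapply(pairs, tracts2, "")), collapse = "|"),
                  ")")

  two_quartet <- paste0("(?:", t2, l19, "){3,}", t2)

  tibble::tibble(
    subtype = c("canonical", "long_loop", "bulge", "two_quartet"),
    stability_rank = 1:4,
    pattern = paste0("(?<!G)(?:", c(canonical, long_loop, bulge, two_quartet),
                     ")(?!G)"))
}

#' Scan a sequence for rG4-forming sites
#'
#' Every maximal locus matching at least one subtype yields exactly one
#' annotation, assigned to the most stable matching subtype
#' (canonical > long_loop > bulge > two_quartet).
#'
#' @param seq RNA string (T is normalised to U; `N` never matches).
#' @param id Sequence identifier carried into the result.
#' @return Tibble with `seq_id`, `start`, `end` (0-based half-open span in
#'   the sequence), `subtype`, `stability_rank`, `matched`, `g_content`,
#'   ordered by `start`.
#' @export
scan_rg4 <- function(seq, id = "seq") {
  if (length(seq) != 1L) stop("scan_rg4() expects a single sequence")
  seq <- as_rna(seq)
  empty <- tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), subtype = character(),
                          stability_rank = integer(), matched = character(),
                          g_content = numeric())
  if (nchar(seq) == 0L) return(empty)

  pats <- rg4_patterns()
  working <- seq
  hits <- list()
  for (i in seq_len(nrow(pats))) {
    m <- gregexpr(pats$pattern[i], working, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- as.integer(m) - 1L
    lens <- attr(m, "match.length")
    for (k in seq_along(starts)) {
      sub <- substr(seq, starts[k] + 1L, starts[k] + lens[k])
      hits[[length(hits) + 1L]] <- tibble::tibble(
        seq_id = id, start = starts[k], end = starts[k] + lens[k],
        subtype = pats$subtype[i], stability_rank = pats$stability_rank[i],
        matched = sub,
        g_content = stringr::str_count(sub, "G") / nchar(sub))
    }
    # mask claimed loci so less stable subtypes cannot re-match them
    for (k in seq_along(starts)) {
      substr(working, starts[k] + 1L, starts[k] + lens[k]) <-
        strrep("#", lens[k])
    }
  }
  if (!length(hits)) return(empty)
  dplyr::arrange(dplyr::bind_rows(hits), .data$start)
}

#' Classify a whole region sequence by its best rG4 subtype
#'
#' Falls back to `g_rich_50` when no subtype matches but the G fraction
#' strictly exceeds 0.5, else `other`.
#'
#' @param seq RNA string.
#' @return One of `canonical`, `long_loop`, `bulge`, `two_quartet`,
#'   `g_rich_50`, `other`.
#' @export
classify_region_sequence <- function(seq) {
  seq <- as_rna(seq)
  if (nchar(seq) == 0L) stop("cannot classify an empty sequence")
  hits <- scan_rg4(seq)
  if (nrow(hits) > 0L) {
    return(hits$subtype[which.min(hits$stability_rank)])
  }
  g_frac <- stringr::str_count(seq, "G") / nchar(seq)
  if (g_frac > 0.5) "g_rich_50" else "other"
}

#' Does an rG4 site overlap a motif span by more than 9 nt?
#'
#' @param rg4_start,rg4_end rG4 site span (0-based half-open).
#' @param motif_start,motif_end Motif span on the same sequence.
#' @return Logical; `TRUE` iff the overlap is at least 10 nt.
#' @export
motif_rg4_overlap <- function(rg4_start, rg4_end, motif_start, motif_end) {
  overlap_length(rg4_start, rg4_end, motif_start, motif_end) > 9L
}
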