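# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check: the rG4 oracle enumerates
# tract/loop decompositions over maximal G-runs, the ARE oracle merges
# intervals to a fixpoint, the folding oracle enumerates every structure
# of the simplified energy model, and the rank-test oracle enumerates
# label assignments.

# maximal G-runs of a sequence as a data.frame(start, end) 0-based half-open
oracle_g_runs <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  is_g <- ch == "G"
  r <- rle(is_g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# units for decomposition: plain runs of length >= min_len, or bulged
# pairs of *consecutive* runs with exact lengths (2,1)/(1,2) and an
# internal gap in bulge_gap (gap chars are automatically non-G)
oracle_units <- function(runs, kind, min_len = 3L, bulge_gap = NULL) {
  if (kind == "plain") {
    keep <- runs$end - runs$start >= min_len
    if (!any(keep)) return(NULL)
    data.frame(start = runs$start[keep], end = runs$end[keep])
  } else {
    out <- NULL
    if (nrow(runs) >= 2L) {
      for (i in seq_len(nrow(runs) - 1L)) {
        l1 <- runs$end[i] - runs$start[i]
        l2 <- runs$end[i + 1L] - runs$start[i + 1L]
        gap <- runs$start[i + 1L] - runs$end[i]
        if (((l1 == 2L && l2 == 1L) || (l1 == 1L && l2 == 2L)) &&
            gap >= bulge_gap[1] && gap <= bulge_gap[2]) {
          out <- rbind(out, data.frame(start = runs$start[i],
                                       end = runs$end[i + 1L]))
        }
      }
    }
    out
  }
}

# does any ordered choice of 4 units (given per-slot unit tables) exist
# with inter-unit gaps within the per-gap bounds?
oracle_chain_exists <- function(slot_units, gap_lo, gap_hi) {
  rec <- function(slot, prev_end) {
    units <- slot_units[[slot]]
    if (is.null(units) || nrow(units) == 0L) return(FALSE)
    for (u in seq_len(nrow(units))) {
      if (slot > 1L) {
        gap <- units$start[u] - prev_end
        if (gap < gap_lo[slot - 1L] || gap > gap_hi[slot - 1L]) next
      }
      if (slot == 4L) return(TRUE)
      if (rec(slot + 1L, units$end[u])) return(TRUE)
    }
    FALSE
  }
  rec(1L, NA)
}

oracle_canonical <- function(runs) {
  u <- oracle_units(runs, "plain", 3L)
  oracle_chain_exists(list(u, u, u, u), rep(1L, 3), rep(7L, 3))
}

oracle_two_quartet <- function(runs) {
  u <- oracle_units(runs, "plain", 2L)
  oracle_chain_exists(list(u, u, u, u), rep(1L, 3), rep(9L, 3))
}

oracle_long_loop <- function(runs) {
  u <- oracle_units(runs, "plain", 3L)
  bounds <- list(lat = c(8L, 12L), cen = c(8L, 21L), std = c(1L, 7L))
  for (long_pos in 1:3) {
    lo <- c(1L, 1L, 1L); hi <- c(7L, 7L, 7L)
    b <- if (long_pos == 2L) bounds$cen else bounds$lat
    lo[long_pos] <- b[1]; hi[long_pos] <- b[2]
    if (oracle_chain_exists(list(u, u, u, u), lo, hi)) return(TRUE)
  }
  FALSE
}

oracle_bulge <- function(runs) {
  plain <- oracle_units(runs, "plain", 3L)
  b17 <- oracle_units(runs, "bulged", bulge_gap = c(1L, 7L))
  b1 <- oracle_units(runs, "bulged", bulge_gap = c(1L, 1L))
  glo <- rep(1L, 3); ghi <- rep(9L, 3)
  # one bulged tract at any of the four positions
  for (pos in 1:4) {
    slots <- rep(list(plain), 4)
    slots[pos] <- list(b17)
    if (oracle_chain_exists(slots, glo, ghi)) return(TRUE)
  }
  # two single-nt-bulged tracts at any two positions
  for (pp in utils::combn(4, 2, simplify = FALSE)) {
    slots <- rep(list(plain), 4)
    slots[pp[1]] <- list(b1)
    slots[pp[2]] <- list(b1)
    if (oracle_chain_exists(slots, glo, ghi)) return(TRUE)
  }
  FALSE
}

# best (most stable) subtype matching anywhere in the sequence, or NA
oracle_best_subtype <- function(seq) {
  runs <- oracle_g_runs(seq)
  if (oracle_canonical(runs)) return("canonical")
  if (oracle_long_loop(runs)) return("long_loop")
  if (oracle_bulge(runs)) return("bulge")
  if (oracle_two_quartet(runs)) return("two_quartet")
  NA_character_
}

# region-level classification mirroring the published fallbacks
oracle_classify <- function(seq) {
  st <- oracle_best_subtype(seq)
  if (!is.na(st)) return(st)
  g <- sum(strsplit(seq, "")[[1]] == "G")
  if (g / nchar(seq) > 0.5) "g_rich_50" else "other"
}

# ---- ARE interval merge oracle --------------------------------------------

# repeatedly merge any two class1/class3 intervals with gap <= 5 until a
# fixpoint; ignores classes other than 1 and 3
oracle_merge_13 <- function(iv, gap = 5L) {
  iv <- iv[order(iv$start), , drop = FALSE]
  repeat {
    done <- TRUE
    i <- 1L
    while (i < nrow(iv)) {
      if (iv$start[i + 1L] - iv$end[i] <= gap) {
        iv$end[i] <- max(iv$end[i], iv$end[i + 1L])
        iv <- iv[-(i + 1L), , drop = FALSE]
        done <- FALSE
      } else {
        i <- i + 1L
      }
    }
    if (done) return(iv)
  }
}

# ---- simplified folding model: exhaustive structure enumeration ------------

# all G4 spans: four complete G-runs (>= tract_min) with gaps 1..loop_max
oracle_g4_spans <- function(seq, tract_min, loop_max, e_quartet) {
  runs <- oracle_g_runs(seq)
  runs <- runs[runs$end - runs$start >= tract_min, , drop = FALSE]
  out <- NULL
  n <- nrow(runs)
  if (n >= 4L) {
    for (cc in utils::combn(n, 4, simplify = FALSE)) {
      gaps <- runs$start[cc[-1]] - runs$end[cc[-4]]
      if (all(gaps >= 1L & gaps <= loop_max)) {
        q <- min(runs$end[cc] - runs$start[cc])
        out <- rbind(out, data.frame(start = runs$start[cc[1]],
                                     end = runs$end[cc[4]],
                                     energy = -e_quartet * q))
      }
    }
  }
  out
}

# exhaustive minimum energy over all legal structures (sets of
# non-crossing pairs plus non-overlapping G4 blocks)
oracle_mfe <- function(seq, g4_aware, e_pair = 1, e_quartet = 7,
                       min_loop = 3, tract_min = 2, loop_max = 7) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  pairs_ok <- function(a, b) {
    p <- paste0(ch[a], ch[b])
    p %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  g4 <- if (g4_aware) {
    oracle_g4_spans(seq, tract_min, loop_max, e_quartet)
  } else NULL
  rec <- function(i, j) {
    if (i > j) return(0)
    best <- rec(i + 1L, j)                      # i unpaired
    for (k in seq_len(j)) {                     # i paired with k
      if (k >= i + min_loop + 1L && pairs_ok(i, k)) {
        best <- min(best, -e_pair + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    if (!is.null(g4)) {                         # G4 block starting at i
      hit <- which(g4$start == i - 1L & g4$end <= j)
      for (h in hit) {
        best <- min(best, g4$energy[h] + rec(g4$end[h] + 1L, j))
      }
    }
    best
  }
  rec(1L, n)
}

# ---- Mann-Whitney enumeration oracle ---------------------------------------

# exact one-tailed P(focal lower) by enumerating all label assignments
oracle_mw_p_less <- function(focal, background) {
  pooled <- c(focal, background)
  n1 <- length(focal)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1, simplify = FALSE)
  us <- vapply(combos, function(cc) {
    sum(r[cc]) - n1 * (n1 + 1) / 2
  }, numeric(1))
  mean(us <= u_obs)
}

# random RNA string helper
random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
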