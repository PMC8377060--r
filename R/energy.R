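# Folding-energy statistic for rG4 formation.
#
# For a window we compute two minimum free energies: dG_dsRNA (secondary
# structure only) and dG_dsRNA_plus_rG4 (the same model extended with
# G-quadruplex states). The rG4 folding-energy statistic is their gap,
#
#   dG_rG4 = dG_dsRNA - dG_dsRNA_plus_rG4  >= 0,
#
# non-negative because the G4-aware state space is a superset of the
# plain one. Both MFEs are also reported normalised by window length.
#
# Two interchangeable energy providers implement the contract
# `engine(seq, g4_aware)` -> MFE in kcal/mol:
#   * internal_fold_engine(): a self-contained simplified model --
#     base-pair maximisation (AU/GC/GU wobble, minimum hairpin loop 3 nt,
#     fixed energy per pair) plus G4 states built from four complete
#     G-runs joined by short loops, worth a fixed bonus per quartet.
#     Deterministic and dependency-free; used throughout the test suite.
#   * external_fold_engine(): adapter to an installed Turner-model MFE
#     program with G-quadruplex support (RNAfold), run at 37 C with
#     `--MEA -p0 -d2 --noLP` (plus `-g` when G4-aware).

pair_matrix <- function() {
  bases <- c("A", "C", "G", "U", "N")
  m <- matrix(FALSE, 5, 5, dimnames = list(bases, bases))
  for (p in list(c("A", "U"), c("G", "C"), c("G", "U"))) {
    m[p[1], p[2]] <- TRUE
    m[p[2], p[1]] <- TRUE
  }
  m
}

# maximal G-runs of a sequence: tibble(start, end) 0-based half-open
g_runs <- function(seq) find_all_matches(seq, "G+")

# candidate G4 elements: four complete G-runs (each >= tract_min) joined
# by loops of 1..loop_max nt; energy = -e_quartet * min(tract length)
g4_candidates <- function(seq, tract_min, loop_max, e_quartet) {
  runs <- g_runs(seq)
  runs <- runs[runs$end - runs$start >= tract_min, , drop = FALSE]
  out <- list()
  nr <- nrow(runs)
  if (nr >= 4L) {
    # successors reachable over a single 1..loop_max nt loop
    succ <- lapply(seq_len(nr), function(i) {
      gaps <- runs$start - runs$end[i]
      which(gaps >= 1L & gaps <= loop_max)
    })
    for (i1 in seq_len(nr)) for (i2 in succ[[i1]]) {
      for (i3 in succ[[i2]]) for (i4 in succ[[i3]]) {
        cc <- c(i1, i2, i3, i4)
        q <- min(runs$end[cc] - runs$start[cc])
        out[[length(out) + 1L]] <- c(start = runs$start[i1],
                                     end = runs$end[i4],
                                     energy = -e_quartet * q)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          energy = numeric()))
  }
  tibble::as_tibble(do.call(rbind, out))
}

#' Internal simplified folding-energy engine
#'
#' Base-pair maximisation with a fixed per-pair energy and, when G4-aware,
#' additional G-quadruplex states (four complete G-runs of at least
#' `tract_min` Gs joined by 1..`loop_max` nt loops) worth
#' `-e_quartet * quartets` where quartets is the shortest chosen tract.
#' Solved exactly by dynamic programming.
#'
#' @param e_pair Energy gain per base pair (kcal/mol, positive number).
#' @param e_quartet Energy gain per G-quartet (kcal/mol, positive
#'   number). The default is large relative to `e_pair` so that a formed
#'   quadruplex outweighs the pairing opportunity cost of its span,
#'   mirroring the strong stabilisation of rG4s in K+ conditions.
#' @param min_loop Minimum hairpin loop length (unpaired nt between a pair).
#' @param tract_min Minimum G-run length usable as a G4 tract.
#' @param loop_max Maximum G4 loop length.
#' @return A function `f(seq, g4_aware = FALSE)` returning the MFE in
#'   kcal/mol (class `fold_engine`).
#' @export
internal_fold_engine <- function(e_pair = 1, e_quartet = 7, min_loop = 3,
                                 tract_min = 2, loop_max = 7) {
  pm <- pair_matrix()
  f <- function(seq, g4_aware = FALSE) {
    seq <- as_rna(seq)
    n <- nchar(seq)
    ch <- strsplit(seq, "")[[1]]
    g4 <- if (g4_aware) {
      g4_candidates(seq, tract_min, loop_max, e_quartet)
    } else {
      tibble::tibble(start = integer(), end = integer(), energy = numeric())
    }
    # E[i, j] = MFE of subsequence i..j (1-based inclusive); padded so
    # that empty spans read 0
    e <- matrix(0, n + 2L, n + 2L)
    pairable <- ch %in% c("A", "C", "G", "U")
    if (n >= 2L) for (len in 2:n) {
      for (i in seq_len(n - len + 1L)) {
        j <- i + len - 1L
        best <- e[i + 1L, j]
        ks <- if (i + min_loop + 1L <= j) seq.int(i + min_loop + 1L, j)
              else integer(0)
        if (length(ks) && pairable[i]) {
          ok <- ks[pm[ch[i], ch[ks]]]
          if (length(ok)) {
            vals <- -e_pair + e[i + 1L, ok - 1L] + e[cbind(ok + 1L, j)]
            best <- min(best, vals)
          }
        }
        if (nrow(g4)) {
          hit <- which(g4$start == i - 1L & g4$end <= j)
          if (length(hit)) {
            best <- min(best, g4$energy[hit] + e[cbind(g4$end[hit] + 1L, j)])
          }
        }
        e[i, j] <- best
      }
    }
    e[1L, n]
  }
  structure(f, class = c("fold_engine", "function"),
            engine = "internal",
            params = list(e_pair = e_pair, e_quartet = e_quartet,
                          min_loop = min_loop, tract_min = tract_min,
                          loop_max = loop_max))
}

#' External Turner-model folding engine (RNAfold adapter)
#'
#' Calls an installed `RNAfold` binary at 37 C with the options
#' `--MEA -p0 -d2 --noLP`, adding `-g` for the G4-aware state space, and
#' parses the MFE from its output.
#'
#' @param binary Path to the RNAfold executable.
#' @return A function `f(seq, g4_aware = FALSE)` (class `fold_engine`).
#' @export
external_fold_engine <- function(binary = "RNAfold") {
  f <- function(seq, g4_aware = FALSE) {
    seq <- as_rna(seq)
    args <- c("--MEA", "-p0", "-d2", "--noLP", "-T", "37", "--noPS")
    if (g4_aware) args <- c(args, "-g")
    out <- tryCatch(system2(binary, args, input = seq, stdout = TRUE,
                            stderr = TRUE),
                    error = function(e) stop("RNAfold failed: ",
                                             conditionMessage(e)))
    m <- regmatches(out, regexpr("\\(\\s*-?\\d+\\.?\\d*\\)\\s*$", out))
    m <- m[nzchar(m)]
    if (!length(m)) stop("could not parse MFE from RNAfold output")
    as.numeric(gsub("[()[:space:]]", "", m[1]))
  }
  structure(f, class = c("fold_engine", "function"), engine = "external")
}

#' Folding energies of a sequence window
#'
#' Populates the dG triple: plain-structure MFE, G4-aware MFE, and their
#' gap `dG_rG4 = dG_dsRNA - dG_dsRNA_plus_rG4`, each also divided by the
#' window length.
#'
#' @param seq RNA string (at least 4 nt).
#' @param engine A `fold_engine`; see [internal_fold_engine()].
#' @param id Sequence identifier.
#' @return One-row tibble with `seq_id`, `length`, `dG_dsRNA`,
#'   `dG_dsRNA_plus_rG4`, `dG_rG4` and the `_norm` variants.
#' @export
fold_energies <- function(seq, engine, id = "seq") {
  seq <- as_rna(seq)
  n <- nchar(seq)
  if (n < 4L) stop("sequence shorter than 4 nt: ", id)
  ds <- tryCatch(engine(seq, g4_aware = FALSE),
                 error = function(e) stop("engine failure on '", id, "': ",
                                          conditionMessage(e)))
  dsg4 <- tryCatch(engine(seq, g4_aware = TRUE),
                   error = function(e) stop("engine failure on '", id, "': ",
                                            conditionMessage(e)))
  tibble::tibble(
    seq_id = id, length = n,
    dG_dsRNA = ds, dG_dsRNA_plus_rG4 = dsg4, dG_rG4 = ds - dsg4,
    dG_dsRNA_norm = ds / n, dG_dsRNA_plus_rG4_norm = dsg4 / n,
    dG_rG4_norm = (ds - dsg4) / n)
}

#' Extend an ARE span by 30 nt on both sides
#'
#' @param start,end ARE span in transcript coordinates.
#' @param tx_length Transcript length (clipping bound).
#' @param extend Extension (nt) applied on each side.
#' @return Integer vector `c(start, end)` of the clipped window.
#' @export
window_for_are <- function(start, end, tx_length, extend = 30L) {
  c(max(0L, start - extend), min(tx_length, end + extend))
}

#' Sample a background gene set
#'
#' Draws `n` genes uniformly without replacement from the eligible pool
#' (genes with no binding site and unchanged TE and mRNA categories),
#' reproducibly under `seed`. Pools smaller than `n` are returned whole
#' with a warning.
#'
#' @param pool Character vector of eligible gene ids.
#' @param n Background size.
#' @param seed Integer seed.
#' @return Character vector of sampled gene ids.
#' @export
sample_background <- function(pool, n = 1000L, seed = 1L) {
  if (length(pool) == 0L) stop("background pool is empty")
  if (length(pool) < n) {
    warning("background pool (", length(pool), ") smaller than n = ", n,
            "; using all pool genes")
    return(pool)
  }
  withr::with_seed(seed, sample(pool, n))
}

#' Compare two energy sets by one-tailed Mann-Whitney test
#'
#' Tests whether the focal set is shifted relative to the background;
#' the default alternative `"less"` asks whether focal values are lower
#' (for signed MFEs: more stable). P values are exact for
#' `min(n1, n2) <= 8` (tie-free case), otherwise the normal approximation
#' with tie correction is used.
#'
#' @param focal,background Numeric vectors (e.g. length-normalised
#'   energies per gene).
#' @param alternative `"less"` or `"greater"` (focal vs background).
#' @return One-row tibble with set sizes, means, `fold_difference`
#'   (mean focal / mean background, `NA` when the background mean is 0),
#'   `U`, `p_value` and a `degenerate` flag (all pooled values identical,
#'   reported as p = 0.5).
#' @export
compare_energy_sets <- function(focal, background,
                                alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(focal) || !length(background)) {
    stop("both sets must be nonempty")
  }
  mf <- mean(focal)
  mb <- mean(background)
  fold <- if (mb == 0) NA_real_ else mf / mb
  pooled <- c(focal, background)
  if (length(unique(pooled)) == 1L) {
    return(tibble::tibble(n_focal = length(focal),
                          n_background = length(background),
                          mean_focal = mf, mean_background = mb,
                          fold_difference = fold, U = NA_real_,
                          p_value = 0.5, degenerate = TRUE))
  }
  exact <- min(length(focal), length(background)) <= 8L
  wt <- suppressWarnings(
    wilcox.test(focal, background, alternative = alternative,
                exact = exact, correct = TRUE))
  tibble::tibble(n_focal = length(focal), n_background = length(background),
                 mean_focal = mf, mean_background = mb,
                 fold_difference = fold, U = unname(wt$statistic),
                 p_value = wt$p.value, degenerate = FALSE)
}
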