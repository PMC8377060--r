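test_that("textbook subtype examples are classified as defined", {
  cases <- list(
    list("GGGAGGGAGGGAGGG", "canonical"),       # four G3 tracts, 1-nt loops
    list("GGAGGAGGAGG", "two_quartet"),         # four G2 tracts
    list("GGGAGGGAGGAGAGGG", "bulge"),          # bulged third tract
    list("GGGAAAAAAAAGGGAGGGAGGG", "long_loop"),# 8-nt lateral loop
    list("GGGAGGGAAAAAAAAAAAAAGGGAGGG", "long_loop")) # 13-nt central loop
  for (cs in cases) {
    hits <- scan_rg4(cs[[1]])
    expect_equal(nrow(hits), 1L, info = cs[[1]])
    expect_equal(hits$subtype, cs[[2]], info = cs[[1]])
    expect_equal(hits$matched,
                 substr(cs[[1]], hits$start + 1, hits$end), info = cs[[1]])
  }
  expect_equal(nrow(scan_rg4("AUAUAUAUAUAU")), 0L)
  expect_equal(nrow(scan_rg4("")), 0L)
})

test_that("a poly-G run yields no spurious quadruplex call", {
  # tract maximality: no decomposition of an uninterrupted run exists
  expect_equal(nrow(scan_rg4(strrep("G", 30))), 0L)
})

test_that("region classification applies the strict >50% G fallback", {
  expect_equal(classify_region_sequence("GGGGGAAA"), "g_rich_50")
  expect_equal(classify_region_sequence("GGGGAAAA"), "other")  # exactly 50%
  expect_equal(classify_region_sequence("GGGAGGGAGGGAGGG"), "canonical")
})

test_that("motif overlap rule requires strictly more than 9 nt", {
  expect_true(motif_rg4_overlap(0, 15, 5, 23))    # overlap 10
  expect_false(motif_rg4_overlap(0, 14, 5, 23))   # overlap 9
  expect_true(motif_rg4_overlap(0, 18, 0, 18))    # identical spans
  expect_false(motif_rg4_overlap(0, 5, 10, 28))   # disjoint
})

test_that("scanner matches the decomposition oracle on random 30-mers", {
  withr::with_seed(20124, {
    # G-biased alphabet so that matches are actually frequent
    seqs <- replicate(1500, random_rna(30, c("A", "C", "G", "G", "U")))
    got <- vapply(seqs, classify_region_sequence, "", USE.NAMES = FALSE)
    want <- vapply(seqs, oracle_classify, "", USE.NAMES = FALSE)
    mismatch <- seqs[got != want]
    expect_equal(length(mismatch), 0L,
                 info = paste(utils::head(mismatch), collapse = ", "))
    expect_equal(got, want)
  })
})

test_that("two-quartet matching depends only on the G-mask (exhaustive)", {
  pat <- rg4_patterns()
  tq <- pat$pattern[pat$subtype == "two_quartet"]
  # all 2^12 G/non-G masks of 12-mers, non-G rendered as A
  masks <- vapply(0:(2^12 - 1), function(mask) {
    paste(ifelse(as.logical(bitwAnd(mask, 2^(0:11))), "G", "A"),
          collapse = "")
  }, "")
  got <- grepl(tq, masks, perl = TRUE)
  want <- vapply(masks, function(s) oracle_two_quartet(oracle_g_runs(s)),
                 logical(1), USE.NAMES = FALSE)
  expect_equal(got, want)
  # and the mask-invariance that extends the result to all 4^12 12-mers
  withr::with_seed(88, {
    seqs <- replicate(2000, random_rna(12, c("A", "C", "G", "G", "U")))
    masked <- gsub("[^G]", "A", seqs)
    expect_equal(grepl(tq, seqs, perl = TRUE),
                 grepl(tq, masked, perl = TRUE))
  })
})

test_that("the stability hierarchy always wins at multi-subtype loci", {
  withr::with_seed(404, {
    loops <- function(n, k) {
      paste(sample(c("A", "U", "C"), k, replace = TRUE), collapse = "")
    }
    for (i in 1:250) {
      # canonical locus also matches two_quartet: canonical must win
      s <- paste0("GGG", loops(1, sample(1:7, 1)),
                  "GGG", loops(1, sample(1:7, 1)),
                  "GGG", loops(1, sample(1:7, 1)), "GGG")
      expect_equal(scan_rg4(s)$subtype, "canonical", info = s)
      # bulge locus also matches two_quartet: bulge must win
      b <- paste0("GGG", loops(1, sample(1:9, 1)),
                  "GGG", loops(1, sample(1:9, 1)),
                  "GG", loops(1, sample(1:7, 1)), "G",
                  loops(1, sample(1:9, 1)), "GGG")
      expect_equal(scan_rg4(b)$subtype, "bulge", info = b)
    }
  })
})

test_that("embedding a canonical rG4 never decreases the site count", {
  withr::with_seed(505, {
    motif <- "GGGAGGGAGGGAGGG"
    for (i in 1:50) {
      bg <- random_rna(60)
      base <- nrow(scan_rg4(bg))
      at <- sample(1:(60 - 16), 1)
      planted <- paste0(substr(bg, 1, at), "C", motif, "C",
                        substr(bg, at + 1, 60))
      expect_gte(nrow(scan_rg4(planted)), base)
      expect_true("canonical" %in% scan_rg4(planted)$subtype)
    }
  })
})

test_that("scanning is deterministic", {
  withr::with_seed(3, s <- random_rna(200, c("A", "C", "G", "G", "U")))
  expect_identical(scan_rg4(s), scan_rg4(s))
})
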