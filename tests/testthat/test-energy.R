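test_that("the dG identity and non-negativity hold on random sequences", {
  eng <- internal_fold_engine()
  withr::with_seed(808, {
    for (i in 1:40) {
      s <- random_rna(sample(10:40, 1), c("A", "C", "G", "G", "U"))
      rec <- fold_energies(s, eng)
      expect_equal(rec$dG_rG4 + rec$dG_dsRNA_plus_rG4, rec$dG_dsRNA)
      expect_gte(rec$dG_rG4, 0)
      expect_equal(rec$dG_rG4_norm, rec$dG_rG4 / nchar(s))
    }
  })
})

test_that("sequences without G tracts have zero rG4 energy gap", {
  eng <- internal_fold_engine()
  rec <- fold_energies("AUAUAUAUAUAU", eng)
  expect_equal(rec$dG_dsRNA, rec$dG_dsRNA_plus_rG4)
  expect_equal(rec$dG_rG4, 0)
})

test_that("a clean canonical quadruplex scores three quartets", {
  b <- 7
  eng <- internal_fold_engine(e_quartet = b)
  rec <- fold_energies("GGGAGGGAGGGAGGG", eng)
  expect_equal(rec$dG_dsRNA, 0)        # no complementary partners
  expect_equal(rec$dG_dsRNA_plus_rG4, -3 * b)
  expect_gte(rec$dG_rG4, 3 * b)
})

test_that("the DP engine equals exhaustive structure enumeration (n <= 20)", {
  eng <- internal_fold_engine()
  withr::with_seed(909, {
    for (n in seq(4L, 20L, by = 2L)) {
      for (rep in 1:4) {
        s <- random_rna(n, c("A", "C", "G", "G", "U"))
        for (aware in c(FALSE, TRUE)) {
          expect_equal(eng(s, aware), oracle_mfe(s, aware),
                       info = paste(s, aware))
        }
      }
    }
    # structured cases where the G4 state is decisive
    for (s in c("GGAGGAGGAGG", "GGGAGGGAGGGAGGG", "GGAGGAGGAGGAGGAGGAGG",
                "CCCCGGGGAAAACCCCGGGG")) {
      for (aware in c(FALSE, TRUE)) {
        expect_equal(eng(s, aware), oracle_mfe(s, aware),
                     info = paste(s, aware))
      }
    }
  })
})

test_that("sequences shorter than 4 nt are rejected", {
  eng <- internal_fold_engine()
  expect_error(fold_energies("GGG", eng), "shorter")
})

test_that("ARE windows extend 30 nt each side and clip at bounds", {
  expect_equal(window_for_are(100, 110, 1000), c(70, 140))
  expect_equal(window_for_are(10, 20, 1000), c(0, 50))
  expect_equal(window_for_are(0, 40, 40), c(0, 40))
})

test_that("background sampling is seeded, exclusive and pool-limited", {
  pool <- sprintf("g%04d", 1:5000)
  a <- sample_background(pool, n = 1000, seed = 13)
  b <- sample_background(pool, n = 1000, seed = 13)
  expect_identical(a, b)
  expect_length(unique(a), 1000L)
  c2 <- sample_background(pool, n = 1000, seed = 14)
  expect_false(identical(a, c2))
  expect_warning(small <- sample_background(pool[1:800], n = 1000, seed = 1),
                 "smaller")
  expect_length(small, 800L)
  expect_error(sample_background(character(), n = 10, seed = 1), "empty")
})

test_that("one-tailed Mann-Whitney matches the enumeration oracle", {
  cmp <- compare_energy_sets(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(cmp$p_value, 0.05)
  expect_equal(cmp$p_value, oracle_mw_p_less(c(1, 2, 3), c(4, 5, 6)))
  withr::with_seed(110, {
    for (i in 1:20) {
      f <- rnorm(sample(3:6, 1))
      b <- rnorm(sample(3:6, 1))
      cmp <- compare_energy_sets(f, b, alternative = "less")
      expect_equal(cmp$p_value, oracle_mw_p_less(f, b), tolerance = 1e-12)
    }
  })
})

test_that("strong planted shifts are detected and ties flagged", {
  withr::with_seed(111, {
    f <- rnorm(50, mean = -3)
    b <- rnorm(1000, mean = 0)
    cmp <- compare_energy_sets(f, b, alternative = "less")
    expect_lt(cmp$p_value, 1e-6)
  })
  deg <- compare_energy_sets(rep(1, 5), rep(1, 8))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0.5)
  expect_equal(compare_energy_sets(c(2, 4), c(1, 2, 3))$fold_difference, 1.5)
  expect_true(is.na(compare_energy_sets(c(1, 2), c(-1, 1))$fold_difference))
})

test_that("null rejection rate of the energy comparison is nominal", {
  withr::with_seed(112, {
    reject <- vapply(1:400, function(i) {
      f <- rnorm(20)
      b <- rnorm(30)
      compare_energy_sets(f, b, alternative = "less")$p_value < 0.05
    }, logical(1))
    # binomial 99% band around 0.05 at 400 reps
    expect_lt(mean(reject), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
  })
})

test_that("the Turner-model adapter obeys the same energy contract", {
  eng <- external_fold_engine()
  rec <- fold_energies("GGGAGGGAGGGAGGGAUAU", eng)
  expect_equal(rec$dG_rG4 + rec$dG_dsRNA_plus_rG4, rec$dG_dsRNA)
  expect_gt(rec$dG_rG4, 0)            # quadruplex stabilises this window
  expect_equal(fold_energies("AUAUAUAUAUGCGC", eng)$dG_rG4, 0)
  expect_lt(eng("GGGGGCCCCCAAAAGGGGGCCCCC", FALSE), -10)
})
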