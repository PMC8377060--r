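test_that("the ZTNB pmf is normalised with consistent moments", {
  r <- 2; p <- 0.3
  k <- 1:100000
  expect_equal(sum(dztnb(k, r, p)), 1, tolerance = 1e-9)
  # truncated mean identity: E[X | X >= 1] = r(1-p)/p / (1 - p^r)
  expect_equal(sum(k * dztnb(k, r, p)),
               r * (1 - p) / p / (1 - p^r), tolerance = 1e-9)
  # upper tail complements the cmf
  expect_equal(pztnb_upper(1, r, p), 1)
  expect_equal(pztnb_upper(5, r, p), 1 - sum(dztnb(1:4, r, p)),
               tolerance = 1e-12)
})

test_that("ZTNB parameters are recovered within 5% at n = 1e5", {
  withr::with_seed(2023, {
    x <- rztnb(1e5, size = 2, prob = 0.3)
    expect_true(all(x >= 1))
    fit <- fit_ztnb(x)
    expect_true(fit$converged)
    expect_equal(fit$size, 2, tolerance = 0.05)
    expect_equal(fit$prob, 0.3, tolerance = 0.05)
    # fitted pmf still normalised
    expect_equal(sum(dztnb(1:1e6, fit$size, fit$prob)), 1, tolerance = 1e-9)
  })
})

test_that("equidispersed counts fall back to a truncated Poisson", {
  expect_warning(fit <- fit_ztnb(rep(3L, 100)), "overdispersed")
  expect_equal(fit$family, "ztpois")
  # the truncated-Poisson mean must reproduce the sample mean
  expect_equal(fit$lambda / (1 - exp(-fit$lambda)), 3, tolerance = 1e-6)
  expect_error(fit_ztnb(1:10), "at least")
  expect_error(fit_ztnb(c(0L, rep(2L, 40))), "positive")
})

test_that("coverage and read binning follow the documented rules", {
  # uniform coverage 3 over 300 nt -> per-bin count 3
  track <- tibble::tibble(chrom = "chr1", start = 0L, end = 300L, value = 3)
  bins <- bin_coverage(track, bin = 100L)
  expect_equal(bins$count, c(3L, 3L, 3L))
  # empty bins are zero
  track2 <- tibble::tibble(chrom = "chr1", start = 250L, end = 300L,
                           value = 2)
  expect_equal(bin_coverage(track2, bin = 100L)$count, c(0L, 0L, 1L))
  expect_error(bin_coverage(tibble::tibble(chrom = "c", start = 0L,
                                           end = 10L, value = -1)),
               "negative")
  # a 50-nt read starting at 120 belongs to bin [100, 200)
  reads <- tibble::tibble(chrom = "chr1", start = 120L, end = 170L)
  expect_equal(bin_reads(reads, bin = 100L)$count, c(0L, 1L))
})

test_that("peak calling finds planted spikes and merges adjacent bins", {
  withr::with_seed(31, {
    counts <- rztnb(500, 2, 0.3)
    mu <- 2 * 0.7 / 0.3
    counts[250] <- round(50 * mu)
    bins <- tibble::tibble(chrom = "chr1",
                           start = (seq_along(counts) - 1L) * 100L,
                           end = seq_along(counts) * 100L,
                           count = counts)
    fit <- fit_ztnb(counts[-250])
    sites <- call_peaks(bins, fit, alpha = 1e-4)
    expect_equal(nrow(sites), 1L)
    expect_equal(c(sites$start, sites$end), c(24900L, 25000L))
    # alpha = 0 calls nothing
    expect_equal(nrow(call_peaks(bins, fit, alpha = 0)), 0L)
    # two adjacent significant bins merge into one 200-nt site
    counts2 <- rep(1L, 100); counts2[c(40, 41)] <- round(20 * mu)
    bins2 <- tibble::tibble(chrom = "chr1",
                            start = (0:99) * 100L, end = (1:100) * 100L,
                            count = counts2)
    sites2 <- call_peaks(bins2, fit, alpha = 1e-4)
    expect_equal(nrow(sites2), 1L)
    expect_equal(c(sites2$start, sites2$end), c(3900L, 4100L))
    expect_equal(sites2$n_bins, 2L)
  })
})

test_that("null false-positive rate stays near the nominal level", {
  withr::with_seed(32, {
    frac <- vapply(1:100, function(i) {
      counts <- rztnb(400, 2, 0.3)
      bins <- tibble::tibble(chrom = "chr1",
                             start = (seq_along(counts) - 1L) * 100L,
                             end = seq_along(counts) * 100L,
                             count = counts)
      fit <- fit_ztnb(counts)
      sig <- call_peaks(bins, fit, alpha = 0.05)
      sum(sig$n_bins) / length(counts)
    }, numeric(1))
    expect_lte(mean(frac), 0.05 + 3 * sqrt(0.05 * 0.95 / (100 * 400)))
  })
})

test_that("planted 10x peaks are recovered with >= 95% sensitivity", {
  withr::with_seed(33, {
    mu <- 2 * 0.7 / 0.3
    hit <- logical(0)
    for (i in 1:10) {
      counts <- rztnb(500, 2, 0.3)
      peak_bins <- sample(seq(10, 490, by = 20), 20)
      counts[peak_bins] <- round(10 * mu) +
        rztnb(length(peak_bins), 2, 0.3)
      bins <- tibble::tibble(chrom = "chr1",
                             start = (seq_along(counts) - 1L) * 100L,
                             end = seq_along(counts) * 100L,
                             count = counts)
      fit <- fit_ztnb(counts)
      sites <- call_peaks(bins, fit, alpha = 0.05)
      hit <- c(hit, vapply(peak_bins, function(b) {
        any(sites$start < b * 100L & sites$end > (b - 1L) * 100L)
      }, logical(1)))
    }
    expect_gte(mean(hit), 0.95)
  })
})

test_that("replicate intersection is symmetric and union-merged", {
  s1 <- tibble::tibble(chrom = "chr1", start = c(100L, 900L),
                       end = c(200L, 1000L), count = c(5L, 7L),
                       p_value = c(1e-3, 1e-4), n_bins = c(1L, 1L))
  s2 <- tibble::tibble(chrom = "chr1", start = 150L, end = 250L,
                       count = 6L, p_value = 1e-2, n_bins = 1L)
  res <- intersect_replicates(s1, s2)
  expect_equal(res$n_rep1_shared, 1L)
  expect_equal(res$n_rep2_shared, 1L)
  expect_equal(c(res$shared$start, res$shared$end), c(100L, 250L))
  expect_equal(res$shared$p_value, 1e-3)
  # symmetry of the shared-locus count
  res_sw <- intersect_replicates(s2, s1)
  expect_equal(res_sw$n_union_loci, res$n_union_loci)
  # identical lists: everything shared; disjoint lists: nothing
  res_id <- intersect_replicates(s1, s1)
  expect_equal(res_id$prop_rep1, 1)
  expect_equal(intersect_replicates(s1, s2[0, ])$n_union_loci, 0L)
})

test_that("identical replicate tracks correlate perfectly in 10-kb bins", {
  track <- tibble::tibble(chrom = "chr1",
                          start = seq(0L, 49900L, by = 100L),
                          end = seq(100L, 50000L, by = 100L),
                          value = rep(c(1, 4, 2, 8, 3), each = 100))
  expect_equal(replicate_coverage_cor(track, track), 1)
})

test_that("sites are assigned to regions by majority with ranked ties", {
  models <- read_transcript_models(write_demo_gtf("+"))
  inside <- tibble::tibble(chrom = "chrT", start = 110L, end = 130L)
  expect_equal(assign_region(inside, models)$region, "5'UTR")
  majority <- tibble::tibble(chrom = "chrT", start = 120L, end = 220L)
  expect_equal(assign_region(majority, models)$region, "CDS")  # 50 CDS nt
  intronic <- tibble::tibble(chrom = "chrT", start = 170L, end = 290L)
  expect_equal(assign_region(intronic, models)$region, "intron")
  intergenic <- tibble::tibble(chrom = "chrT", start = 420L, end = 460L)
  expect_equal(assign_region(intergenic, models)$region, "other")
  expect_true(is.na(assign_region(intergenic, models)$gene_id))
})

test_that("region density is sites per kilobase with sane scaling", {
  models <- read_transcript_models(write_demo_gtf("+"))
  sites <- assign_region(tibble::tibble(chrom = "chrT", start = 110L,
                                        end = 130L), models)
  dens <- region_density(sites, models)
  utr5 <- dens[dens$region == "5'UTR", ]
  expect_equal(utr5$n_sites, 1L)
  expect_equal(utr5$total_length_all, 50L)
  expect_equal(utr5$density_all, 1000 * 1 / 50)
  expect_equal(dens$n_sites[dens$region == "CDS"], 0L)
  expect_equal(dens$density_all[dens$region == "CDS"], 0)
})
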