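# hand-built integrated records used across the tallies tests
demo_records <- function() {
  tibble::tibble(
    gene_id = paste0("g", 1:8),
    bound_5utr = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    bound_cds = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    bound_3utr = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    bound_intron = FALSE,
    bound = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    n_sites = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 0L),
    te_category = c("down", "down", "down", "up", "unchanged", "down",
                    "unchanged", "unchanged"),
    mrna_category = c("unchanged", "unchanged", "unchanged", "unchanged",
                      "up", "unchanged", "unchanged", "unchanged"),
    log2_delta_te = c(-1.4, -1.2, -0.9, 0.8, 0, -1.1, 0.1, 0),
    log2_delta_mrna = c(0, 0.1, -0.1, 0, 0.9, 0, 0, 0),
    expressed = TRUE,
    consistent_trend = TRUE)
}

test_that("region tallies count categories with correct any/only scopes", {
  tal <- tally_by_region_and_category(demo_records())
  u5_te <- tal[tal$region == "5'UTR" & tal$category_type == "te", ]
  expect_equal(u5_te$down[u5_te$scope == "any"], 3L)
  expect_equal(u5_te$up[u5_te$scope == "any"], 1L)
  expect_equal(u5_te$n_genes[u5_te$scope == "any"], 5L)
  # g7 is bound in both 5'UTR and CDS: in "any" of both, in neither "only"
  expect_equal(u5_te$n_genes[u5_te$scope == "only"], 4L)
  cds_te <- tal[tal$region == "CDS" & tal$category_type == "te", ]
  expect_equal(cds_te$n_genes[cds_te$scope == "any"], 2L)
  expect_equal(cds_te$n_genes[cds_te$scope == "only"], 1L)
  # category sums never exceed the bound-gene count in scope
  expect_true(all(tal$up + tal$down + tal$unchanged <= tal$n_genes))
  # only-scope is a subset of any-scope for every region
  for (r in unique(tal$region)) {
    sub <- tal[tal$region == r & tal$category_type == "te", ]
    expect_lte(sub$n_genes[sub$scope == "only"],
               sub$n_genes[sub$scope == "any"])
  }
})

test_that("per-site subtype tallies split by the host gene's TE category", {
  sites <- tibble::tibble(
    chrom = "chr1", start = c(0L, 100L, 200L, 300L),
    end = c(50L, 150L, 250L, 350L),
    gene_id = c("g1", "g2", "g4", "g5"),
    region = c("5'UTR", "5'UTR", "5'UTR", "CDS"))
  seqs <- c("GGGAGGGAGGGAGGG", "GGAGGAGGAGG", "GGGAGGGAGGGAGGG",
            "AUAUAUAUAU")
  tal <- tally_site_subtypes(sites, seqs, demo_records(), region = "5'UTR")
  expect_equal(tal$n_sites[tal$category == "down" &
                             tal$subtype == "canonical"], 1L)
  expect_equal(tal$n_sites[tal$category == "down" &
                             tal$subtype == "two_quartet"], 1L)
  expect_equal(tal$n_sites[tal$category == "up" &
                             tal$subtype == "canonical"], 1L)
  expect_equal(sum(tal$n_sites), 3L)  # the CDS site is out of scope
})

test_that("divergence cells use a strict threshold so the band is closed", {
  rec <- demo_records()
  rec$log2_delta_te <- c(-0.6, 0.585, -0.586, 0, 2, -2, 0.1, 0)
  rec$log2_delta_mrna <- c(0, 0, 0, 0.585, -0.9, 0.7, 0, 0)
  div <- divergence_classes(rec, threshold = 0.585)
  expect_equal(div$te_cell, c("down", "constant", "down", "constant", "up",
                              "down", "constant", "constant"))
  expect_equal(div$mrna_cell, c("constant", "constant", "constant",
                                "constant", "down", "up", "constant",
                                "constant"))
  expect_equal(length(unique(div$cell)), 4L)
})

test_that("KDE summaries integrate to one on their grid", {
  withr::with_seed(330, {
    rec <- tibble::tibble(
      gene_id = paste0("g", 1:120),
      bound_5utr = rep(c(TRUE, FALSE), each = 60),
      bound_cds = FALSE, bound_3utr = FALSE, bound_intron = FALSE,
      bound = rep(c(TRUE, FALSE), each = 60), n_sites = 1L,
      te_category = "down", mrna_category = "unchanged",
      log2_delta_te = rnorm(120), log2_delta_mrna = rnorm(120),
      expressed = TRUE, consistent_trend = TRUE)
    kd <- delta_density_summary(rec)
    u5 <- kd$density[kd$density$region == "5'UTR", ]
    expect_gt(nrow(u5), 0L)
    area <- sum(diff(u5$x) * (u5$y[-1] + u5$y[-nrow(u5)]) / 2)
    expect_equal(area, 1, tolerance = 1e-3)
    # mode near the true centre for a standard normal sample
    expect_lt(abs(u5$x[which.max(u5$y)]), 0.35)
    # small classes are skipped with a note
    expect_true(all(c("CDS", "3'UTR", "intron") %in% kd$skipped))
  })
})

test_that("energy reports compare focal sets against the background", {
  withr::with_seed(331, {
    energies <- tibble::tibble(
      gene_id = paste0("g", 1:60),
      dG_rG4_norm = c(rep(0.08, 10), rep(0, 50)) + runif(60, 0, 1e-3),
      dG_dsRNA_norm = rnorm(60, -0.35, 0.02))
    rep_out <- energy_report(
      energies,
      focal_sets = list(te_down_5utr = paste0("g", 1:10),
                        te_up_5utr = character()),
      background_genes = paste0("g", 11:60))
    expect_equal(unique(rep_out$focal_set), "te_down_5utr")
    g4 <- rep_out[rep_out$statistic == "dG_rG4_norm", ]
    expect_lt(g4$p_value, 0.001)
    expect_gt(g4$mean_focal, g4$mean_background)
  })
})
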