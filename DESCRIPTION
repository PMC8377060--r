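Package: quadte
Title: RNA G-Quadruplex Binding Sites, Folding Energetics and
    Translational Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline linking protein binding sites on mRNA
    (CLIP-seq peaks called with a zero-truncated negative binomial model)
    to RNA G-quadruplex (rG4) structure, AU-rich elements, predicted
    folding energetics, and polysome-profiling translational efficiency.
    Provides rule-based rG4 subtype prediction with a stability hierarchy,
    three-class AU-rich element annotation with interval merging,
    G4-aware minimum-free-energy comparisons against sampled background
    gene sets, transcript-region annotation of binding sites, replicate
    reproducibility checks, translational-efficiency categorisation, and
    a fully seeded synthetic-data generator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
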