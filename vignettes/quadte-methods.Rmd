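---
title: "Methods: rG4 binding, folding energetics and translational efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rG4 binding, folding energetics and translational efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`quadte` chains five analyses that together connect where an
rG4-resolving RNA helicase binds its mRNA targets with what happens to
their translation when the helicase is absent. This vignette documents
the statistical models, the tunable parameters, the numerical choices,
and what the synthetic-data validation does and does not establish.

## Coordinates and sequence model

All intervals inside the package are 0-based, half-open `[start, end)`,
the BED convention; GTF input/output (1-based, closed) converts at the
boundary, and round-trip tests pin this down bit-exactly. A single
internal convention removes the usual off-by-one failure modes when
intersecting peaks, transcript regions and motif spans.

Pattern scanning always operates on the sense (transcribed) strand in
the RNA alphabet: `T` is normalised to `U` on input, minus-strand
intervals are reverse-complemented before scanning, and the ambiguity
code `N` never matches any pattern class (a conservative choice — an
uncertain base is never evidence for a structure).

## rG4 subtype prediction

Four subtypes are scanned with declarative patterns and ranked by
predicted stability:

| rank | subtype | tracts | loops |
|------|---------|--------|-------|
| 1 | canonical | ≥ 4 × G≥3 | 1–7 nt |
| 2 | long-loop | 4 × G≥3 | one loop 8–12 nt (lateral) or 8–21 nt (central), rest 1–7 nt |
| 3 | bulge | 3 × G≥3 + one interrupted tract (`GG H1–7 G`/`G H1–7 GG`, H∈{A,U,C}), or two tracts with single-nt bulges | 1–9 nt |
| 4 | two-quartet | ≥ 4 × G≥2 | 1–9 nt |

A locus matching several subtypes is annotated once, with the most
stable match; whole-region classification falls back to `g_rich_50`
(G fraction strictly above 0.5) and then `other`.

Three points in the published pattern family are under-determined, and
the package fixes them as follows:

* **Central long loops.** The elongated central loop is taken as
  8–21 nt (the prose bound "up to 21 nt"), not 13–21 nt; a printed
  13–21 nt example is read as illustrative. The choice only affects
  loops of 8–12 nt in central position, which are classified long-loop
  rather than unclassified.
* **Bulged-tract position.** The interrupted tract may sit at any of
  the four tract positions (and the two single-nt-bulged tracts at any
  two positions); the published patterns mark one arrangement with
  "e.g.", which we read as exemplary rather than exhaustive.
* **Tract maximality and match semantics.** Because loop characters may
  legally be `G`, a naive regex over a poly-G run would report a ladder
  of overlapping decompositions. The scanner therefore requires every
  tract to be a *complete maximal G-run* (the characters flanking a
  tract within a match are non-G), scans leftmost and non-overlapping
  with lazy loop quantifiers, and masks each claimed locus before
  lower-stability subtypes are scanned. An uninterrupted `G^30` run
  consequently yields no site at all — there is no decomposition whose
  tracts are maximal — which keeps counts interpretable.

These semantics are enforced by an independent oracle: a brute-force
enumerator over maximal-G-run decompositions, checked exhaustively for
the two-quartet class on all 12-mers (via the G-mask factorisation:
two-quartet matching provably depends only on which positions are G)
and on 10⁴ seeded random 30-mers for all classes.

The motif-overlap rule for pairing rG4 sites with 18-nt binding motifs
requires an overlap of strictly more than 9 nt (≥ 10).

## AU-rich elements

Class 1 comprises the W-flank patterns `WWUUUWW`, `WWWUUUWWW`,
`WWWWUUUWWWW` (W ∈ {A,U}) plus a dispersed detector for "several
AUUUA motifs in a U-rich context": ≥ 2 non-overlapping `AUUUA`
pentamers whose bounding span is ≤ 30 nt with a U fraction ≥ 0.5 over
the span. The cluster pattern cited for this class is not reproduced in
the source literature available to us, so the window (30 nt) and U
fraction (0.5) are explicit, exposed parameters rather than hidden
constants. Class 2 is `A(UUUA)k` with k ∈ [2,5] — the only geometry in
which `AUUUA` pentamers can overlap is sharing the bridging `A`
(period 4) — and a run of six pentamers is reported as the capped
five-pentamer match. Class 3 is "more than 5 continuous Us", read
strictly as runs of ≥ 6 U.

When one locus matches several categories the shorter hits are removed
(ties prefer the more specific overlapping-pentamer class), and
surviving class-1/class-3 hits with an inter-interval gap ≤ 5 nt are
merged into a single annotation, exactly the semantics of
`bedtools merge -d 5`. A fixpoint interval-merge oracle verifies that
merged outputs are pairwise separated by more than 5 nt.

## CLIP peak calling

Counts per 100-nt bin are modelled with a single zero-truncated
negative binomial fitted to all nonzero bins. The likelihood is
maximised by BFGS on `(log r, logit p)` — the unconstrained scale keeps
the optimiser inside the parameter space — initialised by method of
moments on the truncated sample. Counts with variance not exceeding
their mean cannot support a negative binomial; the fit then degrades
gracefully to a zero-truncated Poisson limit with a warning, and a
minimum of 30 nonzero bins is required at all. Parameter recovery is
tested at n = 10⁵ draws (within 5% of truth), pmf normalisation to
10⁻⁹, and calibration both under the null (false-positive bin fraction
at α = 0.05 over 100 simulated tracks) and under planted 10×-enriched
peaks (sensitivity ≥ 0.95).

Bin-level P values are ZTNB upper tails P(X ≥ k | X ≥ 1); bins below
α = 0.05 are significant, adjacent significant bins merge into one site
keeping the minimum P. P values are deliberately *not*
multiplicity-adjusted — the published procedure thresholds raw P at
0.05 — but a Benjamini–Hochberg option is available (`adjust = "BH"`).

Two input conventions are supported. For bedGraph coverage, a bin's
count is its coverage area divided by `read_length` (default: the bin
size, under which a track storing per-bin counts round-trips exactly).
For read-interval input, reads are assigned to the bin containing their
start coordinate — the simplest deterministic rule.

Replicate sites sharing ≥ 1 bp are "shared"; shared loci are reported
as the union of the overlapping spans (the union preserves all covered
signal; both the rep1-anchored and union-locus counts are emitted since
published shared-site counts do not disambiguate). Coverage agreement
is summarised by the Pearson correlation of 10-kbp-binned coverage.

Sites are assigned to 5′UTR/CDS/3′UTR/intron by majority overlap with
the genomic footprint of one representative transcript per gene — the
longest mature transcript, a deterministic stand-in for an unstated
isoform choice — with ties broken 5′UTR > CDS > 3′UTR > intron.
Binding density is sites per 1000 nt of region length, reported with
two denominators (all representative transcripts, and bound ones only).

## Folding energetics

For a window the package computes the minimum free energy without G4
states, ΔG⁰(dsRNA), and with them, ΔG⁰(dsRNA+rG4); their difference
ΔG⁰(rG4) = ΔG⁰(dsRNA) − ΔG⁰(dsRNA+rG4) is non-negative whenever the
G4-aware state space contains the plain one, and is zero when no
quadruplex can form. All three are reported per-nucleotide (divided by
the window length). ARE windows are extended 30 nt on each side before
folding and normalised by the *extended* length — the window actually
folded — since the published normalisation does not specify which.

The energy provider is an explicit contract `engine(seq, g4_aware)`:

* `external_fold_engine()` shells out to `RNAfold` at 37 °C with
  `--MEA -p0 -d2 --noLP` (`-g` adds quadruplex states), matching the
  published settings.
* `internal_fold_engine()` is a deliberately simple exact model used by
  the hermetic tests: base-pair maximisation (AU/GC/GU, minimum hairpin
  loop 3 nt, −1 kcal/mol per pair) with G4 states built from four
  complete G-runs of ≥ 2 Gs joined by 1–7 nt loops, scoring
  −7 kcal/mol per quartet (quartets = shortest chosen tract). The
  per-quartet bonus is set large relative to the pair energy so that a
  formable quadruplex outweighs the pairing opportunity cost of its
  span, mirroring the strong K⁺-dependent stabilisation of real rG4s;
  with a small bonus the G4 branch would almost never be optimal and
  the statistic would degenerate to zero. The dynamic program is
  validated against an exhaustive enumeration of all structures for
  sequences up to 20 nt.

Gene-set comparisons use a one-tailed Mann–Whitney test (focal more
stable by default: larger ΔG⁰(rG4) gap, lower dsRNA MFE), exact for
min(n₁,n₂) ≤ 8 and normal-approximated with tie correction otherwise;
all-tied inputs are flagged degenerate with P = 0.5. The background set
is 1000 genes sampled without replacement from genes with no binding
site and unchanged TE and mRNA categories; pools smaller than 1000 are
used whole with a warning. Fold differences of means are undefined
(NA, flagged) when the background mean is zero — which the internal
engine produces by construction on rG4-free backgrounds.

## Translational efficiency

TE = FPKM(polysome)/FPKM(total) per condition and replicate;
ΔTE = TE(KO)/TE(Ctrl). Replicate-averaged FPKMs (arithmetic mean of
the inputs, then the ratio — "averaged FPKM values" describes averaging
inputs, not TEs) give the headline ΔTE. Genes qualify only if both
replicate ΔTEs move strictly in the same direction; a replicate ratio
of exactly 1 has no direction and disqualifies. Per-replicate TEs pair
fractions within a replicate; cross-pairing would manufacture spurious
consistency from shared noise.

Zero denominators get no pseudocount: the gene is kept, flagged, and
excluded from ratios, so the exclusion is auditable. Category
thresholds are inclusive exactly as printed (up: ΔTE ≥ 1.5, down:
ΔTE ≤ 0.66); the stringent subset is strict (log2 ΔTE < −1) with
constant mRNA |log2 ΔFPKM-total| ≤ 0.585; the nine-cell divergence
classification uses strict `> 0.585` so its "constant" band is closed,
consistent with the inclusive 1.5-fold category rule
(0.585 ≈ log2 1.5). The expressed filter for binding-integration
analyses is averaged FPKM-total > 1 in either condition.

Kernel density summaries of log2 ΔTE per exclusive-region class use a
Gaussian KDE with Scott's-rule bandwidth (`stats::bw.nrd`) on a fixed
512-point grid; any standard bandwidth rule would serve, and the choice
is recorded here and in the output. Classes under 5 genes are skipped
with a note; all-identical values are flagged degenerate rather than
smoothed.

## The synthetic-data generator

`generate_synthetic_data()` emits a deterministic function of its
configuration: a transcriptome of 200 two-exon genes (5′UTR 200 nt,
CDS 600 nt split by a 150-nt intron, 3′UTR 300 nt, alternating
strands, 25 genes per chromosome), CLIP coverage for two replicates,
and an FPKM table. The default scenario plants: canonical rG4s in the
5′UTRs of 40 genes (plus 6 bulge and 6 two-quartet genes), CDS peaks in
20 genes, class-2 AREs with 3′UTR peaks in 20 genes; negative-binomial
background bin counts (r = 2, p = 0.3), peak bins at 10× the background
mean in both replicates at the same loci with independent noise;
lognormal baseline FPKMs (median 20, σ = 1 on the log scale) with
multiplicative replicate noise σ = 0.1, ΔTE = 0.4 planted in 80% of
5′UTR-rG4-bound genes (safely below the 0.66 category bound and the
stringent bar), and 2.5×/0.4× mRNA shifts in 10 + 10 unbound genes.

Background sequence is uniform over {A,C,G,U}, then *cleaned*: after
chromosome assembly, any rG4 or ARE hit on either strand that is not
exactly a planted span is redrawn (planted positions are never touched)
until the genome scans clean. Cleaning at the chromosome level, rather
than per region, is essential — independently clean fragments can still
create matches across junctions, and planted motifs can recruit nearby
background G-runs into larger or shifted matches. The cleanup makes
planted-recovery tests exact instead of probabilistic: every
ground-truth label must agree with what the annotators report, with
exact spans.

What passing the synthetic validation shows: the pipeline's inference
is correct and calibrated *under its own model assumptions* — ZTNB
counts, lognormal FPKM noise, structure-free background. What it does
not show: robustness to mappability artifacts, isoform mixtures,
fractional peak overlap with repeats, FPKM estimation error, or any
feature of real libraries upstream of the coverage and FPKM tables,
all of which are out of scope by design.

## Problem sizes and runtime

The shipped validation uses: exhaustive 12-mer masks (4096) plus 10⁴
random 30-mers for the scanner oracle; 1000 sequences for the energy
identity and 3 per length 4–20 for the enumeration oracle; 10⁵ draws
for ZTNB recovery, 100 tracks for null calibration, 200 planted peaks
for sensitivity; 200 seeds for rank-test null uniformity; and the full
200-gene scenario for the end-to-end check. These sizes keep the whole
suite in a few minutes on one CPU while leaving every statistical
tolerance comfortably away from its noise floor.

## Known limitations

* The rG4 taxonomy is rule-based; no thermodynamic scoring (cGcC,
  G4Hunter) is attempted, and antisense DNA G4s are out of scope.
* One representative isoform per gene carries all region annotation;
  genes with heavy isoform switching would need a quantification-aware
  choice.
* The internal energy model is a validation instrument, not a
  thermodynamic predictor; absolute energies are only meaningful from
  the Turner-model adapter.
* The ZTNB model is covariate-free: transcript abundance is not a peak
  covariate, exactly as in the modelled procedure.
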