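---
title: "Models and methods behind cistromer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cistromer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cistromer` bundles the statistical machinery of an integrative
ChIP-seq/RNA-seq study of transcription-factor-driven cell-state
reprogramming: summit-anchored peak annotation, cistrome co-occupancy,
central motif enrichment, differential-expression trajectory clustering,
peak-to-cluster enrichment, and single-hit limiting-dilution analysis.
This vignette explains each model, its assumptions, the tunable parameters
and their defaults, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Coordinates and peak annotation

All internal coordinates are 0-based, half-open (BED convention); GTF
input is converted on read. Every summit-anchored window is half-open on
its downstream edge, so a summit exactly at the downstream boundary falls
outside — one consistent rule instead of per-window conventions.

`classify_peaks()` assigns each peak, via its summit (the pinnacle of
enrichment), to the nearest gene — the minimum of the absolute
summit-to-TSS and summit-to-TES distances, ties broken by
lexicographically smaller gene id — and then to one of seven regions
measured in the direction of transcription: promoter (−5 kb…+0.5 kb of the
TSS), 5′ distal (−15…−5 kb), exon or intron inside the gene body,
3′ proximal (−0.5…+5 kb of the TES), 3′ distal (+5…+15 kb), gene desert
otherwise. For short or nested genes these windows can overlap; precedence
is promoter > exon > intron > 3′ proximal > 5′ distal > 3′ distal. Summit
classification (rather than any-overlap of the whole interval) was chosen
because a single point yields a strict partition and matches the
summit-anchored heatmap and motif analyses; interval overlap remains
available through the co-occupancy functions.

Extended-promoter occupancy (`promoter_occupancy()`, default
−8 kb…+2 kb) is deliberately a separate, wider window: it is the gene-level
"is this promoter bound" call that feeds the multi-factor Venn partitions,
not a peak-level category.

## Co-occupancy and signal

A partner factor is *present* at a primary peak when their intervals share
at least `min_overlap` bp (default 1 bp — the minimal standard criterion;
the threshold is a parameter, not a constant). The class of a peak is the
set of present partners; proportions are reported over all primary peaks
and sum to one. The classification is intentionally asymmetric: it answers
"what fraction of the primary cistrome is co-occupied", and reversing the
roles of the factors answers a different question.

Occupancy correlation re-bins coverage tracks to 10-kb bins by default —
coarse bins stabilize Pearson correlation on sparse point-process-like
signal — and correlates untransformed values (a `log1p` flag exists).
Chromosome-edge bins are excluded pairwise; a constant track has no
defined correlation and is reported `NA` with a warning rather than
silently dropped.

Peak-centered matrices average track bins into ±10-kb windows of 100-bp
columns around each summit, rows sorted by descending peak score (ties by
coordinate) so the heatmap top is the strongest binding. Non-promoter
profiles first remove peaks whose summit lies in any extended promoter,
then RPKM-normalize the track (`value × 1e9 / (bin_bp × total signal)`,
treating total track mass as mapped-read mass) and report the column mean
with a percentile bootstrap band over peaks (default 1000 resamples).

## Motif scanning and central enrichment

Scores are log2 odds of the motif model against a background base
composition (uniform by default; an estimated 0-order background is a
parameter). A pseudocount of 1e-4 keeps probabilities positive. The score
threshold at level α is calibrated **exactly**: the null distribution of
the score of a random background word is computed by dynamic programming
over scores rounded to a 0.001 grid, and the threshold is the smallest
grid score whose upper tail is ≤ α. The DP is exact up to the rounding
grid; the test suite checks it against exhaustive enumeration of all 4^m
words for m ≤ 8 at 1e-9.

Scanning evaluates both strands and keeps at most one site per sequence:
the maximum score at or above threshold, ties broken by smaller absolute
offset from the sequence center, then leftmost, then plus strand. The
best-site-per-sequence convention (rather than all sites) is the package's
reading of "sites per peaks" counting; it makes the fraction of peaks with
a site well-defined. One practical consequence drove the design of the
bundled example PWMs: motifs whose columns are all equally informative
produce a lattice of identical scores, ties become common, and the
central tie-break then fabricates positional signal. Real motifs have
heterogeneous information content and effectively continuous scores, so
`example_pwms()` uses per-position confidences with an uneven split of the
off-consensus mass.

Central enrichment follows the CentriMo logic: with n sites among
`L − m + 1` possible site centers, each odd central window of width w
contributes the binomial upper tail `P(X ≥ k(w) | n, w/(L − m + 1))`, and
the reported p is the minimum over windows times the number of windows
tested (Bonferroni), capped at 1. The correction makes the null
conservative, which the suite verifies over 500 uniform-placement
simulations. Because centrally planted sets reach p-values far below
double-precision underflow, the statistic also reports `log10_p` computed
on the log scale.

## Differential expression and trajectory clusters

The test is a conditional negative-binomial exact test. Counts are scaled
to a common library size and rounded; for one gene with group sums
(a, b), replicate counts n_A, n_B and common dispersion φ, the group sums
are negative binomial with sizes n_A/φ and n_B/φ and a shared success
probability, so the conditional distribution of a given a + b is free of
the unknown mean. The two-sided p-value sums the probabilities of all
outcomes no more likely than the observed one. The common dispersion is
the pooled method-of-moments ratio `Σ(var − mean)/Σ(mean²)` across genes
and groups, floored at 1e-4; with single-replicate groups a dispersion
must be supplied.

Library sizes are *effective* sizes by the median-of-ratios method rather
than raw totals. Total-count scaling is exactly what breaks when
differential expression is asymmetric — the shift leaks into every null
gene — while median-of-ratios stays calibrated; the suite verifies both
the nominal size (type-I error within [0.03, 0.07] at α = 0.05 over null
simulations) and power above 0.9 for 4-fold changes under the
differential-expression rule. Fold changes are `(mean CPM + 0.5)` ratios;
the rule itself — fold change strictly above 1.5 in either direction and
p strictly below 0.05 — is applied per condition, and the union of genes
passing in at least one condition forms the clustering input, with
untested conditions imputed as zero and flagged.

Trajectories (log2 fold change versus control across the four conditions
in time order) are clustered by agglomerative hierarchical clustering with
Euclidean distance and Ward linkage (`ward.D2`), cut at k = 6 — the number
of visually distinct patterns in the reference analysis; k is a parameter.
log2 fold change versus control (not z-scored expression) is the default
clustering space because it is what the trajectory archetypes are defined
on; a z-score variant can be built by the caller from the CPM matrix.
Rows are sorted by gene id before clustering and clusters relabelled by
first appearance, so the partition is deterministic and invariant to input
order. Centroids map to archetypes with a dead band δ = 0.2 log2 units:
persistently repressed (all entries < −δ), persistently activated (all
> δ), early-up-then-down (first > δ, last < −δ), gradually induced
(monotone non-decreasing, last > δ), else other.

## Peak-to-cluster enrichment

A gene carries an occupancy class when at least one summit of that class
lies strictly within 50 kb of the gene span (gene-body anchored — the
inclusive reading of "within ±50 kb of each peak"; a TSS-anchored variant
is a one-line `class_label`/window change). Enrichment of each cluster in
each class is the one-sided hypergeometric (Fisher) test on the 2×2 table
over the background universe, which defaults to the *tested* genes with
coordinates — the expressed-gene universe, since untested genes can never
enter a cluster. Odds ratios use the Haldane +0.5 correction when a single
cell is zero; a table with a degenerate margin (for example every
background gene carrying the class) has no estimable contrast and reports
OR = 1 with p = 1. Benjamini–Hochberg control is applied across the whole
cluster × class grid; raw p-values are reported alongside.

## Limiting dilution

Under the single-hit Poisson model a dose of d cells takes with
probability `1 − exp(−d·f)`. The log-likelihood is concave in f, so the
bisection-safeguarded Newton iteration (relative tolerance 1e-12)
converges to the global maximum; the single-dose case reduces to the
closed form `−log(1 − k/n)/d`, which the suite checks at 1e-9.
Confidence intervals are 95% profile-likelihood sets
`{f : 2(ℓ(f̂) − ℓ(f)) ≤ 3.841}` — preferred over Wald intervals because
the designs are small and the estimate often sits near a boundary. With
no takes anywhere the boundary estimate f = 0 is reported with the
explicit one-sided upper limit; with takes in every animal the likelihood
is unbounded and the fit reports infinity with a lower limit and a
warning. Group comparison is the likelihood-ratio test of a pooled versus
group-specific frequency on χ²(1); incidence comparison is Pearson χ²
without continuity correction, with cells of zero expectation contributing
nothing so that identical saturated incidences give a statistic of 0
rather than NaN.

Two properties of this design are worth knowing. First, at the reference
transplant design (doses of 1000 and 10,000 cells, 10 animals each) the
per-experiment maximum-likelihood estimate carries a small-sample upward
bias of roughly 14% — an inherent property of the MLE at 121 possible
outcomes, not an implementation artifact; the estimator is consistent, and
the suite verifies recovery within 5% on pooled replicate tables. Second,
because the outcome space is that small, interval *coverage* can be
computed exactly by enumerating the outcome probabilities instead of
Monte-Carlo simulation; the acceptance checks do exactly that and find
coverage within [0.93, 0.97] at frequencies of 1/500, 1/2000 and 1/20000.

## The synthetic-data generators

One global seed fans out to fixed per-generator substreams, so each
component is independently reproducible and every generator emits
machine-readable truth tables. Default scales mirror the study design:
a 2 × 10-Mb genome with 500 genes; three factors with co-occupancy
fractions 0.52 / 0.19 / 0.08 / 0.21 (three-way, +AR, +FOXA1,
primary-only — chosen to reproduce the published proportions of ~71% AR
overlap, >50% AR+FOXA1 co-occupancy and ~21% primary-only peaks); peak
widths uniform on 200–600 bp (typical TF ChIP-seq scale) with anchors
jittered ≤ 50 bp so peaks of one anchor always overlap and anchors on a
2-kb grid so distinct anchors never do; Gaussian signal enrichment of
sd 150 bp over Poisson background; sequences of 1001 bp with sites planted
at Normal(0, 20 bp) offsets in central mode; negative-binomial counts
(dispersion 0.1, log-normal baselines around 100, library factors
±20%) over two groups × four conditions with triplicates except a
duplicate for the treated group at the second time point, exactly as in
the reference design; six trajectory templates with peak effect 1.5 log2
units covering the archetype vocabulary; and a planted tumor-initiating
frequency of 1/2000 at doses of 1000 and 10,000 cells with 10 animals per
dose. The expression universe (2000 genes) deliberately exceeds the
simulated genome's gene count: the first 500 ids are the genomic genes,
mirroring the fact that an expression assay covers far more genes than any
simulated genomic region.

What the generators do **not** emulate: read-level sequencing noise,
mappability and GC structure, realistic genome sequence beyond base
composition, peak-width/score correlation, tag-shift artifacts, batch
effects in counts, or inter-animal heterogeneity in transplants. Passing
tests therefore demonstrate that the *statistical machinery* recovers
planted structure under the stated noise models, not that the pipeline is
robust to every artifact of real sequencing data.

## Problem sizes and determinism

The default end-to-end run (2 chromosomes × 10 Mb, 500 genes, 5000 peaks
per factor, 800 motif sequences, 2000 × 23 counts) completes in well under
a minute on one CPU and is byte-identical across repeated runs with the
same seed; the test suite exercises recovery at up to 20,000 peaks and
the acceptance script re-runs every measurement from scratch. Simulation
study sizes in the suite (20 null seeds for test calibration, 500
centrality nulls, 10 clustering seeds, 50 enrichment seeds, 200
limiting-dilution contrasts) were chosen to keep Monte-Carlo error well
below each criterion's margin.

## Known limitations

* Nearest-gene annotation ignores enhancer–promoter looping; the ±50 kb
  integration window is a proximity heuristic, not a target-assignment
  model.
* The exact test uses a single common dispersion; gene-wise or trended
  dispersion (as mature DE packages provide) is out of scope.
* The motif module scans known PWMs; de novo discovery belongs to
  dedicated tools.
* The single-hit model assumes independent initiation events and
  homogeneous cells per group; multi-hit and frequency-heterogeneity
  models are not implemented.
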