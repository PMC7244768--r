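---
title: "Methods: from ligation products to lymphoma subtype calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ligation products to lymphoma subtype calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtmis)
```

## The assay and its data model

RT-MLPA sequencing quantifies a targeted gene panel on cDNA. For each
marker, two half-probes hybridize side-by-side across an exon junction; a
ligase joins them only when both are bound, and the ligated product is
PCR-amplified and sequenced. Each probe carries a random 7-nt unique
molecular identifier (UMI), so however many PCR copies of a captured
molecule are sequenced, they share a UMI and count once. The data model in
`rtmis` follows this chemistry:

* a `PanelDefinition` holds the probe catalog: marker, gene, functional
  group, pair index and half-probe sequences. Four genes (AICDA, BCL6,
  MYC, BCL2) carry two independent probe pairs; paired variant/reference
  probes (group `MUTATION`) report somatic hotspot mutations and virus
  status and are *not* expression markers. The packaged panel reports 137
  expression markers; with the four dual pairs and eight variant/reference
  locus pairs it comprises 157 probe rows.
* a `UmiCountMatrix` holds deduplicated molecule counts plus per-sample QC
  (totals, discard categories, the interpretability flag);
* an `ExpressionMatrix` holds normalized values at probe or gene level.

The counting convention for "137 markers" is: distinct genes outside the
`MUTATION` group, dual-pair genes counted once. Because the assay's
oligonucleotide sequences are proprietary, the packaged panel carries
synthetic placeholder half-sequences drawn at a fixed seed and screened so
that any two ligation products differ at eight or more positions; every
read-level result in this package is therefore about the *procedure*, not
about the real probes.

## Read matching and molecular counting

The default read layout is UMI first (offset 0, length 7) followed
immediately by the ligated insert; universal adapters are assumed trimmed
upstream, and sample demultiplexing is the sequencer's job (one FASTQ per
sample). A read is assigned to the probe pair whose left half matches at
the insert start within `max_mismatches` (default 2, no indels) and whose
right half matches immediately after. Two rules keep counting honest:

* if two probes tie for the best match of a half, the read is discarded
  (`no_match`) rather than guessed — ambiguity must not inflate counts;
* if the best left and right halves come from different probe pairs the
  read is a ligation `chimera` and is counted separately.

A mismatch budget of 2 per ~28-nt half absorbs ordinary sequencer error
(at 0.5–1% per base, most reads have 0–1 errors per half) while staying
far below the ≥ 8 inter-product distance, so mis-assignment is effectively
impossible on the packaged panel. Base qualities are ignored: the Hamming
budget already absorbs what quality trimming would remove. An
implementation note: reads whose halves match a probe exactly are resolved
by a hash lookup, which is provably equivalent to the general
minimum-Hamming rule when all half-sequences are unique and fixed-length
(as in the packaged panel); only inexact reads take the generic scan.

Deduplication counts distinct UMIs per (sample, marker). The default is
exact dedup; `umi_collapse = "hamming1"` additionally merges a UMI into a
more abundant one at Hamming distance 1 when the parent count is at least
`2·child − 1` (the standard directional network rule), absorbing
sequencing errors inside the UMI itself at a small risk of merging true
molecules. A sample is *interpretable* when its summed deduplicated count
reaches 5000 molecules — the floor under which per-marker averages (1–40
molecules per marker at this panel size) become too shallow to interpret.
The total is taken over all markers, i.e. the sum of per-marker distinct
UMIs, not the number of globally distinct 7-mers: at several thousand
molecules over a 4^7 = 16384-sequence UMI space, collisions across markers
are expected and must not be conflated with duplicates.

## Normalization and dual-probe aggregation

Counts are converted to `log2(1 + 10^4 · count/total)` where `total` is
the sample's summed count over expression markers. The pre-log relative
abundances sum to one per sample, making values exactly invariant to
sequencing depth — necessary because the interpretability floor admits an
order-of-magnitude depth spread between samples. The scale factor 10^4
puts one molecule in 5000 at `log2(3) ≈ 1.6`, comfortably inside the
dynamic range. Mutation-group probes are excluded from both the matrix and
the denominator (their abundance tracks genotype, not expression) and are
instead reported as variant fractions `variant/(variant+reference)` with
default calling thresholds of fraction ≥ 0.1 at depth ≥ 20 molecules —
defaults surfaced in the interface, since no canonical values exist for
this chemistry.

Genes with two probe pairs get the arithmetic mean of their two pair
values on the log scale. No probe-dropping rule is attempted: a failed
probe should be visible in QC, not silently absorbed.

## The subtype classifier

The seven-class forest (ABC, GCB, PMBL, FL, MCL, SLL, and MZL merging
nodal/splenic MZL, MALT and LPL) is trained on gene-level normalized
expression with Gini splits, 5000 trees, maximum depth 20, minimum node
size 4, `sqrt(p)` candidate features per split and bootstrap resampling.
The per-class probability is the fraction of trees voting for the class —
the natural uncertainty readout of a voting ensemble — and the call is the
argmax, ties broken deterministically by the canonical label order. An
optional "unclassified" band is deliberately absent by default: the
intended use forces a call on every sample, and the probability vector
itself carries the ambiguity. The training seed is part of the model
configuration and is stored in the model file, making retraining
bit-reproducible. The train/validation split is stratified by subtype at a
2/3 fraction; stratification (rather than a simple random split) keeps the
small classes represented in both cohorts, at the cost of not reproducing
exactly a published unstratified randomization — per-class training counts
are `round(2/3 · n_class)`.

Fitting uses the `ranger` forest implementation; `min.node.size = 4`
mirrors a minimum-samples-to-split of 4. Vote fractions are obtained from
per-tree predictions rather than probability trees, so probabilities are
exact multiples of `1/n_trees`.

## Exploratory statistics

The volcano analysis runs Welch's unequal-variances t-test per gene on the
log-scale values (the scale on which the noise is closest to Gaussian) and
computes the fold change on de-logged relative abundances with a 0.5
pseudo-molecule so zero-count genes stay finite. Significance combines
|log2 FC| > 1 with Benjamini–Hochberg FDR < 0.05. PCA standardizes genes
to unit variance before decomposition (so high-abundance markers do not
dominate), fixes component signs by making the largest-|loading| gene
positive, and reports the 40 genes with the largest Euclidean loading norm
over the first two components as the map's "most discriminatory" markers.
Wilcoxon comparisons use the exact two-sided distribution for groups of at
most 25 without ties and the tie-corrected normal approximation otherwise.

## Survival analyses

Follow-up is administratively censored at 60 months: stored times are
capped and events beyond the cap are recoded as censored. Kaplan–Meier
curves carry Greenwood-variance 95% CIs on the log(−log) scale (guaranteed
inside [0, 1]); group differences use the log-rank test; the multivariate
model is a Cox proportional-hazards fit with the Efron tie approximation
(accurate for the heavily tied month-resolution times), with a warning
when events are fewer than ten per covariate.

Threshold scanning dichotomizes a marker at each expression quantile from
0.10 to 0.90 in steps of 0.05 — a bounded grid that avoids tiny strata at
the extremes — and reports the cut with the smallest log-rank p-value.
This minimum is *not* corrected for the multiplicity of thresholds tried;
the scan mirrors exploratory clinical practice, is labeled exploratory in
its output, and returns the full p-vector so users can correct. The
MYC/BCL2 double-expressor flag is the conjunction of the two per-gene
dichotomizations; scanning operates on normalized expression (the scale on
which thresholds transfer across depths), with overall survival as the
default endpoint.

## The synthetic-data generator

`simulate_cohort` encodes each subtype as a template of expected marker
abundances mixed with a microenvironment: per sample it draws a tumor
purity from the template's range, mixes the tumor profile with T-cell,
Tfh, macrophage and cytotoxic component vectors at template-specific
weights, perturbs each marker by lognormal noise, and draws molecule
counts multinomially at a lognormal per-sample depth. The templates are
hand-authored from qualitative signature knowledge — FL combines a GCB
profile with a Tfh-rich microenvironment and near-exclusive sterile
Iε–Cε transcription; MCL is CCND1/SOX11/CD5-high and CD10/CD23-low; ABC is
IGHM/AICDA-high with sterile Iμ–Cμ low; PMBL is
PDL1/PDL2/JAK2/CD30/CD23-high; SLL is CD5/CD23-high; MZL carries a
post-germinal-center marginal-zone profile — not fitted to any dataset.

Default conditions, chosen once as a realistic operating point: 40 samples
per class (matching the order of per-class sizes in real training
cohorts), median depth 20000 molecules with lognormal sigma 0.4 (a
comfortable multiple of the 5000 floor, with realistic spread), biological
noise sigma 0.6 (marker abundances typically vary ~2× around the
template), per-base read error 0.005, chimera rate 0.01, and geometric PCR
duplication with mean 4 — the duplicate multiplicity is deliberately
irrelevant to molecule counts, which is the point of UMI dedup, and any
supported mean must leave counts invariant. `simulate_fastq` inverts the
read processor (UMI + ligation product, duplicates, substitution errors,
injected chimeras, shuffled order) and is the identity under
`count_fastq` at zero error. `simulate_survival` draws exponential event
times with per-covariate hazard multipliers (default hazard ratio 2.0 for
the double-expressor flag, the magnitude reported for MYC/BCL2 dual
expression), exponential censoring, and the 60-month cap.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: FFPE RNA degradation and probe-specific
capture efficiencies (real inter-marker biases), batch and run effects,
intermediate or ambiguous histologies (every simulated sample is a clean
draw from one template), borderline tumor purities below the template
ranges, and correlated marker noise. Classifier accuracies on this
generator are upper bounds of separability under the encoded signatures,
not estimates of clinical accuracy.

## Numerical choices and degenerate inputs

* Read-matching ties discard the read; argmax ties in prediction take the
  first class in canonical order; both are deterministic.
* Zero-variance genes are dropped (with a warning) before PCA; a fully
  constant matrix yields zero coordinates and zero explained variance
  rather than an error.
* Welch tests on genes with zero variance in both groups return `NA` and
  are flagged untested; BH adjustment runs over tested genes only.
* Threshold scanning errors on constant expression ("degenerate grid");
  splits that leave a stratum empty are skipped as untestable.
* `n_per_class = 0` simulations return empty cohorts without error;
  empty FASTQ files yield all-zero, non-interpretable rows.
* Seeds: every stochastic operation takes an explicit seed (simulation
  config, forest config, split), and the pipeline writes its full
  configuration and an md5 manifest next to its artifacts, so reruns are
  byte-identical.

## Problem sizes used in the checks

The packaged checks run the classifier at 40 samples per class with
500-tree forests (vote resolution 0.002, ample for accuracy assertions —
the 5000-tree default changes resolution, not behavior), read-level
oracle checks on ten seeded fixtures of ≥ 10000 reads, Cox recovery at
n = 500, and threshold-scan recovery over 100 replicates of n = 200.
These sizes make the whole suite run in well under a minute of compute
per module while leaving the statistical assertions sharp.

## Known limitations

Indel-tolerant alignment is out of scope (a read with an insertion in a
half-probe is discarded, slightly deflating counts at high indel rates);
cross-run calibration and batch correction are not attempted; the
mutation-calling thresholds are pragmatic defaults, not validated cutoffs;
and the real assay's probe sequences, cohorts and outcome data are not
distributed, so all end-to-end results in this package are on synthetic
data by construction.
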