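---
title: "Inferring bacterial transcription units from strand-specific RNA-seq"
author: "TUfinder authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring bacterial transcription units from strand-specific RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

A bacterial transcription unit (TU) is the stretch of DNA transcribed as
one RNA molecule: one promoter, one terminator, and one or more genes in
between. Unlike operons — static gene groupings predicted from sequence
alone — TUs are condition-dependent: the same genome expresses different
TU structures under different growth conditions, and only transcriptomic
data can reveal them. TUfinder infers the TU structure active in a given
strand-specific RNA-seq sample.

The observable signal is the per-base, per-strand read abundance: because
a transcript is one molecule (prematurely terminated fragments are
rapidly degraded by ribonucleases), an expressed TU should show roughly
*continuous* coverage across its whole span, including the short
intergenic stretches between its genes, and roughly *constant level*
across its genes. Conversely, a boundary between two TUs typically shows
a coverage gap and/or an expression fold change. TUfinder turns these two
signals — continuity and variance — into features of every junction
between consecutive same-strand genes, and classifies each junction as
co-transcribed or not with a radial-basis support vector machine (SVM).
Maximal runs of co-transcribed junctions become the predicted TUs, which
always partition the gene set.

## Automatic training data

No large gold standard of experimentally verified TUs exists for most
bacteria, so training labels are constructed from the data themselves:

* **Negatives** (junctions between distinct TUs): consecutive same-strand
  pairs where *both* hold — more than 50% of the intergenic positions
  have zero coverage, *and* the two genes' mean expression levels differ
  by more than 10-fold. The conjunction keeps negatives conservative.
* **Positives from spanning evidence**: when long reads (or paired-end
  fragment spans) are available, a pair whose entire intergenic region is
  contained in at least one single read, with gene expression within
  2-fold (inclusive), is certifiably co-transcribed.
* **Constructed positives**: spanning reads of ~225 bp cannot certify
  junctions with longer intergenic regions, so additional positives are
  carved out of single genes. A gene is an ideal miniature TU: one
  molecule, continuous coverage. Each gene is partitioned into a left
  pseudo-gene, a pseudo intergenic region (cIR), and a right pseudo-gene.
  The cIR length is `round(p|g|)` with `p` drawn from the empirical
  distribution of the ratio `|ir| / (|ir| + |g_left| + |g_right|)` over
  eligible pairs (same strand, no opposite-strand gene in between), so
  constructed junction geometry follows the genome's real junction
  geometry. A second draw `q`, from the distribution of
  `||g_left| - |g_right|| / (|ir| + |g_left| + |g_right|)`, sets the
  freedom to shift the cIR off-center.

### Where the cIR is placed

Real intergenic sequence is AT-richer than coding sequence (in the kind
of genome this method targets, GC ≈ 0.33 vs 0.40), so the cIR is placed
on the GC-minimal window of the gene: candidate start offsets range over
`[m - p|g|/2 - q|g|/2, m - p|g|/2 + q|g|/2]` around the gene midpoint
`m` — a window of width `q|g|` centred on the position that would split
the gene evenly — clamped so that both flanks keep at least one base,
and the start minimizing the window GC fraction is chosen, leftmost on
ties (determinism). We fix this window parameterization as a design
decision of the package: it gives `q` exactly the role its defining
ratio suggests — the larger the typical length difference between
neighbouring genes, the farther off-centre a constructed junction may
sit.

A constructed pair is kept only if it resembles a genuinely expressed
co-transcribed pair: cIR zero-coverage fraction ≤ 0.5, flank expression
ratio ≤ 10, and cIR length ≥ 225 bp. The length floor makes constructed
positives complementary to spanning-read positives rather than redundant
with them: they specifically cover the long-intergenic-region regime the
225 bp reads cannot certify. We read the three exclusion rules as a
single keep-iff-all-pass test; genes too short to partition are skipped.

### Empirical resampling, not smoothing

`p` and `q` are drawn by resampling the observed ratios with replacement
rather than from a kernel density estimate. Resampling is
assumption-free, exactly testable (the sampler's mean must converge to
the observations' mean), and avoids a bandwidth choice with no data to
calibrate it.

## Features

Each candidate junction (real pair or constructed pair) yields six
features:

| feature | meaning |
|---|---|
| `gapCount` | intergenic positions with zero abundance |
| `gapFraction` | the same as a fraction of intergenic length |
| `log2FcLeftIr` | log2 mean fold change, left flank vs intergenic |
| `log2FcRightIr` | log2 mean fold change, right flank vs intergenic |
| `log2FcLeftRight` | log2 mean fold change between the flanks |
| `normVariance` | variance of per-base abundance across the whole span, after dividing by the span mean |

A pseudocount of 1 guards every ratio and logarithm (zero coverage is
routine at junction boundaries). `normVariance` divides by `mean + 1`,
making it exactly 0 for constant coverage and scale-free up to the
pseudocount. The gene–gene fold change is included alongside the two
flank-vs-intergenic fold changes because the labeling filters themselves
operate on it; the classifier is free to down-weight redundant
components. Zero-length intergenic regions (abutting or overlapping
genes) get `gapFraction = 0` by definition — there is nothing between
the genes to be uncovered.

Before training, each feature is min–max scaled to `[0, 1]` with bounds
fitted on the training set and reused at prediction: RBF kernels need
commensurate scales, and `gapCount` is unbounded while `gapFraction`
lives in `[0, 1]`.

## Classifier and assembly

The SVM uses a radial-basis kernel with the customary defaults:
`cost = 1`, `gamma = 1/6` (one over the number of features), equal class
weights — all configurable. Model quality is reported as stratified
five-fold cross-validation accuracy with a seeded fold assignment, plus
the ROC over held-out decision scores. Two training modes exist:
`illumina_only` (constructed positives only — for datasets with no
long-read companion) and `illumina_plus_long_read` (constructed plus
spanning-evidence positives); with the same negatives the second mode's
positive set is a superset of the first's.

Junction predictions are chained into TUs per strand: maximal runs of
positively classified junctions become multi-gene TUs, everything else
is a single-gene TU. Junctions with an opposite-strand gene inside the
intergenic region are classified like any other by default (they are
excluded only from the density fitting above); `splitOnOpposite = TRUE`
forces them negative. Overlapping TUs are out of scope: each prediction
partitions the genes.

## Evaluation procedures

* **Confirmed TUs**: a run of genes whose full span (first start to last
  end) lies inside at least one single long read is independently
  confirmed. **Sensitivity** is the fraction of confirmed runs recovered,
  where "recovered" means every internal junction of the run is predicted
  co-transcribed — a confirmed run may legitimately sit inside a longer
  predicted TU, since short reads cannot certify the full TU extent.
* **Similarity of two TU sets**: the Jaccard index of their
  joined-junction sets (consecutive same-strand pairs placed in one TU).
  It is symmetric, 1 on identical sets, and defined as 1 when neither
  set joins anything.
* **Depth resampling**: reads are subsampled without replacement to a
  grid of target depths, the fixed trained pipeline is re-run per
  subsample, and sensitivity is averaged over replicates. Resampling
  operates on reads (not coverage positions) so that the subsample is a
  realizable sequencing experiment; at full depth the subsample is the
  entire read set and the full-data result is reproduced bit-exactly.
* **Intergenic contrast**: intergenic regions inside predicted TUs
  should be expressed, those between TUs should not; a one-sided
  rank-sum test quantifies the contrast without distributional
  assumptions.

## The simulator

`simulateGenome()` / `simulateCoverage()` / `simulateEvidence()` generate
a genome with *known* TU structure, so that every pipeline stage can be
tested against exact ground truth without downloads. Defaults emulate the
kind of dataset the method targets:

* ~0.9 kb lognormal gene lengths; ~50 bp gaps within TUs, heavier-tailed
  ~200 bp gaps between TUs (real between-TU regions carry promoters and
  terminators and reach kilobases — the heavy tail also produces
  junction geometries whose constructed-pair analogues exceed 225 bp);
* TU sizes 1–5+ with 56% single-gene TUs and about a quarter of
  multi-gene TUs at five-plus genes;
* coding GC 0.40 vs intergenic GC 0.33;
* per-TU lognormal expression (sd 1 on the log scale), 50 bp reads at
  100X estimated depth with gamma overdispersion (CV 0.3) on per-TU
  counts;
* hard boundaries: 85% of between-TU gaps stay coverage-free, the rest
  are covered by transcriptional read-through — so the classifier sees
  both easy and hard junctions and cannot saturate trivially;
* ~0.5% antisense reads; 225 bp strandless long reads and 170 bp
  stranded fragment spans sampled inside true TU spans (never crossing a
  boundary).

What the simulator does **not** model: base-call or mapping error
(inputs are mapped intervals), positional coverage biases (GC bias,
3'/5' decay), transcription start/stop site micro-structure, and
overlapping TUs. Passing tests on synthetic data therefore demonstrates
the correctness and statistical behaviour of the machinery under the
stated generative assumptions, not performance on any particular real
dataset.

## Numerical choices and degenerate inputs

* Coordinates are 1-based closed intervals throughout, the
  GRanges/IRanges convention, converted at file boundaries (GFF3 and
  GenBank are already 1-based; BED/bedGraph are converted on import and
  export).
* Expression level of a region = mean per-base abundance on its strand;
  fold change = ratio of means with pseudocount 1, larger over smaller
  where a direction-free ratio is needed.
* GC minimization ties break leftmost; empty candidate windows after
  clamping collapse to the nearest feasible start; infeasible genes are
  skipped.
* `estimatedDepth()` divides the coverage mass of the whole genome (both
  strands) by the length of the *union* of gene intervals, so
  overlapping annotations are not double-counted.
* The decision-score orientation is fixed (larger = more positive), so
  ROC endpoints are meaningful: a perfectly inverted ranking gives AUC
  0, not 0.5.
* Seeded entry points (`simulate*`, `constructCTUs`, `trainTUModel`,
  `depthResample`) evaluate under a temporary RNG state and restore the
  caller's, so library code never clobbers a user's random stream.

## Problem sizes used in the test suite

The packaged tests run the full pipeline on a ~700-gene (~0.7 Mb)
simulated genome at 100X — large enough for stable five-fold
cross-validation and several hundred junctions, small enough for a
single-CPU desk run; oracle-equivalence sweeps use hundreds of random
miniature instances (tens of genes, hundreds of bases). The depth
titration uses 8 depths from 0.1X to 100X with 5 replicates each.

## Known limitations

* One replicon at a time; multi-contig inputs should be split and
  processed per contig.
* Sensitivity of the negative filter to the 10-fold/50% thresholds is
  inherited from the labeling rules; at very low depth the gap filter
  mislabels lowly expressed co-transcribed pairs, which is exactly the
  degradation the depth-resampling analysis quantifies.
* Scores are SVM decision values, not calibrated probabilities.
* No promoter/terminator sequence information is used; boundaries are
  inferred from coverage alone.
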