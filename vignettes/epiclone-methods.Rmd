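---
title: "Methods: genetic and epigenetic clonal evolution in relapsed AML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic and epigenetic clonal evolution in relapsed AML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiclone)
library(dplyr)
```

Relapsed acute myeloid leukemia (AML) can evolve along two intertwined
axes: the somatic driver mutations a patient's leukemia gains or loses
between diagnosis and relapse, and the chromatin accessibility landscape
that rewires even when the mutations do not change. `epiclone` implements
a complete analysis pipeline for paired diagnosis/relapse samples across
both axes — mutation-dynamics classification and survival, bulk and
single-cell ATAC-seq comparison, projection onto a healthy hematopoietic
reference, and mitochondrial-variant clone tracing with a test for
convergent epigenetic evolution — together with a synthetic-data module
that generates every input with planted ground truth.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic data does and
does not emulate.

## Mutation dynamics and clonal bins

Each variant carries a variant allele frequency (VAF) at diagnosis
(`vaf_dx`) and relapse (`vaf_rel`). The classification rule is a fixed
pair of thresholds:

* **gained**: `vaf_dx < 0.05` and `vaf_rel > 0.10`;
* **lost**: `vaf_dx > 0.10` and `vaf_rel < 0.05`;
* **stable**: everything else.

Both inequalities are strict — a VAF of exactly 0.05 or 0.10 can never
trigger gain or loss. The asymmetric band (detection floor 0.05, call
threshold 0.10) buffers the call against sampling noise near the
detection limit; a variant absent at diagnosis that reaches a relapse
VAF in (0.05, 0.1] is deliberately classified stable, because it never
clears the call threshold. Variants whose VAF is not quantifiable
(FLT3-ITD, NPM1 insertions) are classified from absent/present calls
instead. Tier 3 variants (synonymous or of unknown significance) are
removed before classification, and a patient is evaluable only when
every remaining variant has both timepoint values.

Patients are binned from their mutation classes: `Stable` (no gained,
no lost), `Gain`, `Loss`, or `GainAndLoss`; *unstable* clonality means
any bin other than `Stable`. Relapse-free survival is compared between
stable and unstable patients with a Kaplan–Meier/log-rank analysis and a
Cox proportional-hazards model adjusted for age and sex. Ties use the
Efron approximation; patients missing age or sex are dropped from the
adjusted model with a warning; covariates that are constant in the
analysis set are dropped rather than letting the fit fail.

```{r clonal-example}
cfg <- sim_config(seed = 1, n_patients = 200)
cohort <- simulate_mutation_cohort(cfg)
bins <- cohort$mutations |>
  filter_evaluable_patients() |>
  classify_mutations() |>
  bin_patients()
table(bins$bin)
glance(compare_survival(bins, cohort$clinical))
```

## Bulk chromatin accessibility

**Cut sites.** Each ATAC fragment contributes two Tn5 insertion sites,
`start + 4` and `end - 5` in 0-based coordinates, the standard
correction for the 9-bp duplication Tn5 leaves behind. All interval
arithmetic in the package is 0-based half-open (BED convention).

**Consensus peaks.** Per-sample 500-bp fixed-width peaks are merged by
iterative removal: rank all peaks by significance score, keep the best,
discard everything overlapping it, repeat. Ties are broken by
(chromosome, start) so the result is deterministic. Blacklisted regions
are removed first, and a consensus peak must be supported by calls from
at least two biological samples ("samples", not technical replicates —
the support rule is about reproducibility across libraries). The result
is pairwise disjoint by construction.

**Similarity.** A patient's diagnosis/relapse similarity is the Pearson
product-moment correlation across all peaks between the two timepoints'
profiles, where each profile is the mean of its replicates' CPM vectors.
Averaging on the CPM scale (not raw counts) keeps a deeper replicate
from dominating the profile. The same routine compares LSC vs non-LSC
compartments by swapping the comparison column.

**Differential accessibility.** Counts are modelled per feature with a
negative-binomial GLM containing a timepoint effect and patient fixed
effects (so within-patient pairing absorbs between-patient baseline
differences), median-of-ratios size factors, empirical-Bayes dispersion
shrinkage toward a mean–dispersion trend, a Wald test on the timepoint
coefficient and Benjamini–Hochberg adjustment — the DESeq2 model with
default parameters, which this package wraps rather than re-derives.
On degenerate inputs whose gene-wise dispersions are all within two
orders of magnitude of the minimum (possible in small synthetic
fixtures), no trend is estimable and the fit falls back to the gene-wise
dispersion estimates. All-zero features are excluded and reported `NA`.

**Locus scan.** To find chromosomal regions with an excess of
significant peaks, windows (default 100 kb, stepping 50 kb — sized after
the ~100-kb co-regulated blocks this kind of scan is meant to catch)
are tested per direction with a one-sided binomial test of the in-window
significant count against the genome-wide significant fraction, BH
adjusted; windows with fewer than 5 peaks are skipped. The window
geometry and the binomial form are this package's declared choice; the
underlying question (is this window enriched relative to the global
rate?) fixes the test only up to such details.

**Motif enrichment** is a hypergeometric tail test per motif of
foreground vs background peak annotation, reported in both enrichment
and depletion directions. PWM scanning is out of scope; the peak×motif
annotation is an input.

## Gene accessibility scores

Gene-level accessibility uses a 5-kb tile matrix and an exponential
distance decay. For a gene with span `[TSS − 5000, TTS]` (strand decides
which end is the TSS):

* tiles overlapping the span weigh `1 + e^{-1}`;
* flanking tiles at distance `d` weigh `e^{-d/5000} + e^{-1}`;
* tiles farther than 20,000 bp, or overlapping another gene's span,
  weigh 0.

`d` is measured between nearest interval edges, which makes the weight
continuous at the body/flank boundary (`d = 0` gives `1 + e^{-1}` from
either side — asserted numerically in the tests). "Overlapping another
gene" is formalized as intersecting the other gene's `[TSS − 5kb, TTS]`
span. Tile counts are depth-normalized per sample as
`counts × 10^4 / total insertions` (the scale constant is arbitrary but
fixed; scores are invariant to joint rescaling of counts and depth),
multiplied by the weights and summed per gene.

**Relapse signature.** Genes are ranked by the relapse-vs-diagnosis
statistic from the clonally stable patients; the top 500 and bottom 500
form the signature (an even, never-overlapping split shrinks when fewer
than 1,000 genes are ranked). A cell's **relapse chromatin score** is
the sum of its accessibility over the top genes minus the sum over the
bottom genes — linear in the gene-score matrix, and exactly zero for a
cell with equal mass on both halves.

## Pre-ranked GSEA

The enrichment score is the extremum of the weighted Kolmogorov–Smirnov
running sum with weight exponent 1: member genes increment by their
normalized `|stat|`, non-members decrement by `1/(N − N_h)`. Ranking
ties are broken by gene name, so results are reproducible. The null is
gene-label permutation — `n_permutations` random same-size sets — with
the signed convention: the p-value and normalized ES (NES) are computed
against the same-sign half of the null, so `sign(NES) = sign(ES)`. A
set containing *every* ranked gene has no complement term and carries no
information; its ES is defined as 0. Sets with fewer than 5 ranked
members are skipped. The permutation seed is a required argument. The
implementation is cross-checked in the tests against an independent
step-by-step running sum (agreement to 1e-12) and against
`fgsea::calcGseaStat`.

## Projection to a healthy reference

The healthy hematopoietic reference is reduced by latent semantic
indexing (LSI): counts are binarized, term frequencies are
depth-normalized binary profiles scaled by `10^4`, the inverse document
frequency is `log(1 + N_cells / n_cells_with_feature)`, and a truncated
SVD supplies the components. Component 1 is dropped when its correlation
with log depth exceeds 0.75 in magnitude — in sparse single-cell ATAC
the first component usually encodes library size. The default is 25
retained components, single-pass (not iterative) LSI.

Query cells are *projected*: TF-normalized with the reference's IDF and
multiplied onto the stored singular vectors, never refit. Projection is
therefore linear and invariant to query depth. Bulk samples enter this
space via pseudo-single cells: 250 cells per sample by default, each a
10,000-read subsample of the bulk cut-site pool (without replacement
within a cell, with replacement across cells). The closest-normal call
for each query cell is the majority label among its k = 10 nearest
reference cells in LSI space (Euclidean), ties resolved toward the
label with the smaller mean distance.

## Single-cell analysis

Cells pass QC on fragment count, fraction of reads in peaks, and an
upstream doublet flag (doublet scoring itself is out of scope).
Clustering builds a shared-nearest-neighbour graph (k = 20, Jaccard
edge weights, edges below 1/15 pruned) and optimizes modularity
(Louvain) at a user resolution; fixed seeds give fixed partitions.

Residual healthy immune cells are removed by a two-criterion rule that
formalizes what is usually a manual call: a cluster is a contaminant
only if (a) its mean marker-panel accessibility (default panel: the
T/B/monocyte markers CD89, TLR4, GZMA, CD247, TCL1, CD37, CD209)
exceeds the rest of the sample by more than 2 pooled SDs **and** (b) its
mean pseudobulk correlation to the other clusters falls below the 5th
percentile of inter-cluster correlations. Requiring both keeps
marker-high but epigenetically ordinary clusters. As a safety rail the
filter refuses to remove more than half the cells unless forced.

Cluster-to-cluster chromatin similarity uses summed (pseudobulk) counts,
CPM normalization and Pearson correlation across peaks, with diagnosis
and relapse clusters compared jointly so relapse-like diagnosis
subpopulations surface.

## Mitochondrial clone tracing

Somatic mitochondrial variants act as endogenous barcodes. Variant QC
keeps a variant only if it is detected in **more than 3** cells, its
strand correlation exceeds **0.65**, and its mean coverage exceeds
**10** reads — strict inequalities. Strand correlation is the Pearson
correlation of per-cell alt counts between strands, over cells with at
least one read on each strand (the exact formula is not fixed by the
upstream tooling; this is the package's declared form). Heteroplasmy is
`alt / (alt + ref)`, missing at zero coverage.

Cells are clustered into **mitoclones** on the heteroplasmy matrix
binarized at 0.1 (a cell is variant-positive at ≥ 10% heteroplasmy),
using the same SNN/Louvain machinery; the resolution is an explicit
parameter with a sweep helper, since this choice is made manually in
practice. Mean heteroplasmy per (variant, cluster) is reported and
clusters whose best variant sits below 0.1 are flagged as potentially
noise-driven.

The clone hierarchy comes from containment of variant presence sets
(presence = mean heteroplasmy ≥ 0.2): variants present in all clones
form the root; a clone descends from the clone with the largest strictly
contained set; non-nesting candidates are reported as conflicts and can
be resolved with a manual override table. Clone frequencies per
timepoint feed a continuity-corrected two-proportion z-test per clone to
flag expansions and contractions.

**Convergent epigenetic evolution.** Per timepoint, all off-diagonal
clone-pair pseudobulk correlations are collected; diagnosis and relapse
collections are compared by an unpaired two-sample t-test. Convergence
is declared when the relapse mean exceeds the diagnosis mean at
p < 0.05 — independently arising clones ending up in more similar
chromatin states after therapy. A complementary statistic,
`clone_shift_concordance()`, correlates clones' per-feature
`log2((CPM_rel + 1)/(CPM_dx + 1))` shift vectors: high concordance means
distinct clones moved the same way.

```{r mito-example}
mito <- simulate_mito_scatac(sim_config(seed = 3, n_mito_cells = 200),
                             convergence = "on")
hp <- compute_heteroplasmy(mito$alt_fw, mito$alt_rev,
                           mito$ref_fw, mito$ref_rev)
keep <- filter_mito_variants(hp$stats)$variant
clones <- cluster_mitoclones(hp$heteroplasmy[keep, ],
                             cell_meta = mito$cells,
                             resolution = 0.5, seed = 1)
glance(convergence_analysis(clones$assignments, mito$peak_counts))
```

## The synthetic-data module

Every generator is a pure function of its configuration (including the
seed): identical inputs give byte-identical outputs, and planted truth
is always returned alongside the data. Downstream recovery tests consume
only the data and touch the truth solely in their assertions.

Defaults encode the study conditions the package models, chosen once:

* **Mutation cohort**: 200 patients, bin probabilities
  (0.43, 0.20, 0.17, 0.20) for Stable/Gain/Loss/Gain+Loss, 1–8 mutations
  per patient drawn from a recurrent-AML-gene panel, ~25% of FLT3/NPM1
  events non-quantifiable. Clinical covariates: age ~ Normal(60, 10)
  truncated to [18, 90], sex Bernoulli(0.5), relapse times exponential
  with a 1.56-fold hazard for Stable patients (median ~300 days for
  Unstable), 10% censoring — enough signal for the survival stage to
  recover.
* **Bulk cohort**: 10 patients × 2 timepoints × 2 technical replicates
  over 20,000 peaks; log-normal per-peak baselines around a geometric
  mean of 50 counts, per-patient peak-level effects, negative-binomial
  noise with dispersion 0.1 (the noise model is the package's choice —
  the original analyses ran on real data), and a 500-peak signature
  shifted by log2FC 1 at relapse (two-thirds opening, one-third
  closing).
* **Healthy reference**: a 5-type hematopoietic hierarchy
  (HSC → CMP → {GMP → Mono, MEP}), 200 cells per type over 2,000 peaks;
  30% housekeeping peaks shared by all types, a private enriched block
  per type, and parents borrowing part of each child's block so the
  hierarchy yields graded similarity.
* **Mito simulation**: a rooted 4-clone default tree whose children
  inherit parental variants, heteroplasmy 0.8, ~20× coverage per variant
  per cell, 1,000 cells per timepoint. Strand coverages share a
  per-cell log-normal depth factor — that shared variation is what makes
  genuine variants strand-concordant — while planted artifact variants
  put their reads on one strand per cell and are exactly what the QC
  filter must remove. Convergence mode mixes every clone's relapse
  chromatin profile 70% toward one shared relapse state; stationary mode
  keeps clone profiles identical across timepoints, which is the null
  the calibration tests exercise.

What the generators do **not** emulate: alignment artifacts, duplicate
structure, GC or mappability bias, batch effects, doublets, copy-number
change, or mitochondrial variant drift within a clone. Passing
recovery tests therefore demonstrates that the algorithms are correct
and calibrated under their stated models, not that real libraries meet
those models.

## Problem sizes and numerical choices

The test and acceptance workloads use deliberately compact instances:
2,000-feature null cohorts and 20,000-feature power cohorts for the
differential stage, 1,500-peak references with 600 cells, 150–1,000
mito cells per timepoint, and 25–50 simulation seeds for power and
calibration estimates. These sizes were chosen so every property that
matters (type-I error in [0.03, 0.07], ≥ 80% recovery of the planted
signature, ≥ 90% held-out label accuracy, mitoclone ARI ≥ 0.95,
convergence power ≥ 90% with size ≤ 10%) is measured with comfortable
margins at desk scale.

Other numerical decisions: CPM columns sum to 10^6 exactly up to
floating point; zero-variance vectors make correlations *errors*, never
silent `NA`s; the LSI SVD seed is scoped internally so refits are
identical without disturbing the caller's RNG; k-NN label ties break by
mean distance; merge ties break by genomic position; GSEA ranking ties
break by gene name.

## Known limitations

* The mutation classifier assumes VAFs comparable across timepoints;
  copy-number change under a variant shifts VAF without a true clonal
  change and is not modelled (karyotype can be folded in upstream as an
  override).
* The locus scan's binomial windows are a declared stand-in for an
  unspecified regional test; window size and step are tunable.
* Iterative (multi-pass) LSI and batch correction are out of scope;
  embeddings are used uncorrected, as the projection approach expects.
* The containment tree builder reports, rather than resolves,
  non-nesting variant sets; resolution is manual by design.
* Clustering-based mitoclone recovery needs clones large enough to form
  their own neighbourhoods (k = 20); very rare clones (fractions of a
  percent) are detected through their variant profiles and frequency
  tests, not through unsupervised clustering.
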