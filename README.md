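# epiclone

Genetic and epigenetic clonal evolution analysis for relapsed acute
myeloid leukemia (AML).

Many AMLs relapse without any change in their driver mutations, which
raises the question of what *does* change. `epiclone` is an R toolkit
for paired diagnosis/relapse samples that analyzes both evolutionary
axes side by side, for computational biologists working with targeted
genotyping, bulk/single-cell ATAC-seq and mitochondrial scATAC-seq:

* **Clonal evolution from VAFs** — every mutation is classified
  *gained* (VAF < 0.05 at diagnosis → > 0.10 at relapse), *lost* (the
  reverse) or *stable*; patients are binned Stable / Gain / Loss /
  Gain+Loss, and relapse-free survival of stable vs unstable patients
  is compared by Kaplan–Meier, log-rank, and an age/sex-adjusted Cox
  model (HR for stable clonality).
* **Bulk chromatin evolution** — Tn5 cut sites (+4/−5 shift), iterative
  merging of 500-bp fixed-width peaks into a disjoint consensus set,
  per-patient diagnosis↔relapse Pearson similarity of replicate-averaged
  CPM profiles, DESeq2-backed differential accessibility with patient
  covariates, a binomial locus window scan, overlap fractions between
  differential sets (LSC vs non-LSC), and hypergeometric motif
  enrichment.
* **Gene accessibility scores** — the exponential-decay tile model
  (body weight `1 + e^-1`, flank weight `e^(-d/5000) + e^-1`, zero
  beyond 20 kb or at gene collisions), a top/bottom-500 relapse
  signature, per-cell relapse chromatin scores, and pre-ranked GSEA
  with a gene-permutation null.
* **Projection to healthy hematopoiesis** — TF-IDF latent semantic
  indexing of a healthy single-cell reference, projection of query (or
  250 pseudo-single-cell) profiles without refitting, and
  closest-normal cell-type calls from the 10 nearest reference cells.
* **Mitoclone tracing** — variant QC (> 3 cells, strand correlation
  > 0.65, coverage > 10), heteroplasmy clustering into mitoclones,
  containment-based clone trees, per-clone frequency dynamics with
  expansion tests, and an unpaired t-test asking whether clones are
  more similar to each other at relapse than at diagnosis —
  *convergent epigenetic evolution*.

A first-class synthetic-data module (`sim_config()`, `simulate_*()`)
generates every input with planted ground truth, so the full pipeline
runs and is tested entirely offline.

## Worked example

```r
library(epiclone)

cohort <- simulate_mutation_cohort(sim_config(seed = 1))
bins <- cohort$mutations |>
  filter_evaluable_patients() |>
  classify_mutations() |>
  bin_patients()
table(bins$bin)
#>      Stable        Gain        Loss GainAndLoss
#>          94          41          38          27

compare_survival(bins, cohort$clinical)
#> Relapse-free survival, stable vs unstable clonality
#>   n = 200 patients, 181 events
#>   log-rank p = 0.007085
#>   Cox HR (stable vs unstable, age/sex adjusted) = 1.508 [1.108, 2.053], p = 0.009006
```

Of 200 simulated patients, 94 (47%) kept an unchanged driver-mutation
complement at relapse, and those clonally stable patients relapsed
significantly faster: the generator plants an exponential relapse-time
model with a stable-vs-unstable hazard ratio of 1.56, and the Cox fit
recovers 1.51 with a confidence interval covering the truth.

The epigenetic arm on the same seed:

```r
bulk <- simulate_bulk_chromatin_cohort(sim_config(seed = 1))
summary(timepoint_similarity(bulk$counts, bulk$samples)$r)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.9017  0.9096  0.9115  0.9123  0.9160  0.9260

res <- differential_accessibility(bulk$counts, bulk$samples)
sig <- res$feature[!is.na(res$padj) & res$padj < 0.05]
length(sig)                              # 535 peaks at padj < 0.05
mean(bulk$truth$peak %in% sig)           # 0.986 of the planted signature
```

Each patient's diagnosis and relapse profiles stay highly correlated
(r ≈ 0.91) while the differential stage still pinpoints the planted
500-peak relapse signature: 98.6% recovered at padj < 0.05 with few
false peaks. Result objects have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures (Kaplan–Meier curves, volcano plots,
similarity heatmaps, clone frequency dynamics).

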