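# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth, so downstream recovery is testable
# without any sequencing data. All generators are pure functions of
# (config, seed).

#' Simulation configuration
#'
#' Collects the knobs shared by the generators. Defaults describe the study
#' conditions the package models: a ~200-patient relapsed-AML meta-cohort
#' with 43% clonally stable patients, a 10-patient bulk ATAC cohort with a
#' 500-peak relapse signature at log2FC 1, a small hematopoietic reference
#' hierarchy, and a four-clone mitochondrial tree at heteroplasmy 0.8 and
#' ~20x per-variant coverage.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_patients Patients in the simulated mutation meta-cohort.
#' @param bin_probabilities Named 4-vector of probabilities over
#'   `Stable`, `Gain`, `Loss`, `GainAndLoss`; must sum to 1.
#' @param n_peaks,n_genes Feature counts for the bulk chromatin cohort.
#' @param signature_size Number of peaks shifted at relapse (planted
#'   signature); must not exceed `n_peaks`.
#' @param effect_log2fc Planted relapse shift, in log2 units.
#' @param nb_dispersion Negative-binomial dispersion of peak counts
#'   (variance = mu + dispersion * mu^2); must be positive.
#' @param mean_peak_count Geometric-mean expected Tn5 count per peak.
#' @param n_bulk_patients,bulk_replicates Bulk cohort layout (two technical
#'   replicates per sample by default).
#' @param celltypes Tibble with columns `celltype`, `parent` (NA for the
#'   root) describing the healthy reference hierarchy.
#' @param cells_per_type,n_ref_peaks Reference size.
#' @param clone_tree_spec Tibble with columns `clone`, `parent`, `variants`
#'   (list-column of variant ids; children inherit the parent's set),
#'   `freq_dx`, `freq_rel` (each timepoint summing to 1).
#' @param n_mito_cells Cells per timepoint in the mito simulation.
#' @param mean_mito_coverage Mean reads per variant per cell.
#' @param heteroplasmy Heteroplasmy of a clone's defining variants, in
#'   `[0, 1]`.
#' @param n_artifact_variants Planted strand-biased artifact variants that
#'   the QC filter must remove.
#' @param hr_stable Planted hazard ratio for relapse of Stable vs Unstable
#'   patients (relapse times are exponential).
#' @param censor_prob Probability a patient's relapse time is censored.
#' @return A validated list of class `epiclone_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 200L,
                       bin_probabilities = c(Stable = 0.43, Gain = 0.20,
                                             Loss = 0.17, GainAndLoss = 0.20),
                       n_peaks = 20000L,
                       n_genes = 2000L,
                       signature_size = 500L,
                       effect_log2fc = 1,
                       nb_dispersion = 0.1,
                       mean_peak_count = 50,
                       n_bulk_patients = 10L,
                       bulk_replicates = 2L,
                       celltypes = default_celltype_hierarchy(),
                       cells_per_type = 200L,
                       n_ref_peaks = 2000L,
                       clone_tree_spec = default_clone_tree(),
                       n_mito_cells = 1000L,
                       mean_mito_coverage = 20,
                       heteroplasmy = 0.8,
                       n_artifact_variants = 2L,
                       hr_stable = 1.56,
                       censor_prob = 0.1) {
  bins <- c("Stable", "Gain", "Loss", "GainAndLoss")
  if (length(bin_probabilities) != 4 ||
      abs(sum(bin_probabilities) - 1) > 1e-9 ||
      any(bin_probabilities < 0)) {
    abort("`bin_probabilities` must be 4 non-negative values summing to 1",
          class = "epiclone_config_error")
  }
  if (is.null(names(bin_probabilities))) names(bin_probabilities) <- bins
  if (nb_dispersion <= 0 || mean_mito_coverage <= 0 || mean_peak_count <= 0) {
    abort("rates and dispersions must be positive",
          class = "epiclone_config_error")
  }
  if (signature_size > n_peaks) {
    abort("`signature_size` cannot exceed `n_peaks`",
          class = "epiclone_config_error")
  }
  if (heteroplasmy < 0 || heteroplasmy > 1) {
    abort("`heteroplasmy` must lie in [0, 1]",
          class = "epiclone_config_error")
  }
  for (tp in c("freq_dx", "freq_rel")) {
    if (abs(sum(clone_tree_spec[[tp]]) - 1) > 1e-9) {
      abort(sprintf("clone `%s` frequencies must sum to 1", tp),
            class = "epiclone_config_error")
    }
  }
  structure(
    list(seed = as.integer(seed), n_patients = as.integer(n_patients),
         bin_probabilities = bin_probabilities,
         n_peaks = as.integer(n_peaks), n_genes = as.integer(n_genes),
         signature_size = as.integer(signature_size),
         effect_log2fc = effect_log2fc, nb_dispersion = nb_dispersion,
         mean_peak_count = mean_peak_count,
         n_bulk_patients = as.integer(n_bulk_patients),
         bulk_replicates = as.integer(bulk_replicates),
         celltypes = celltypes, cells_per_type = as.integer(cells_per_type),
         n_ref_peaks = as.integer(n_ref_peaks),
         clone_tree_spec = clone_tree_spec,
         n_mito_cells = as.integer(n_mito_cells),
         mean_mito_coverage = mean_mito_coverage,
         heteroplasmy = heteroplasmy,
         n_artifact_variants = as.integer(n_artifact_variants),
         hr_stable = hr_stable, censor_prob = censor_prob),
    class = "epiclone_sim_config"
  )
}

#' @rdname sim_config
#' @export
default_celltype_hierarchy <- function() {
  tibble(
    celltype = c("HSC", "CMP", "GMP", "MEP", "Mono"),
    parent = c(NA, "HSC", "CMP", "CMP", "GMP")
  )
}

#' @rdname sim_config
#' @export
default_clone_tree <- function() {
  tibble(
    clone = c("c0", "c1", "c2", "c3"),
    parent = c(NA, "c0", "c0", "c2"),
    variants = list("m1A>G", c("m1A>G", "m2C>T"), c("m1A>G", "m3G>A"),
                    c("m1A>G", "m3G>A", "m4T>C")),
    freq_dx = c(0.40, 0.25, 0.25, 0.10),
    freq_rel = c(0.40, 0.25, 0.25, 0.10)
  )
}

# Recurrently mutated AML genes used to label simulated variants; weights
# roughly follow relative mutation frequency in relapsed cohorts.
aml_panel_genes <- function() {
  tibble(
    gene = c("NPM1", "DNMT3A", "FLT3", "RUNX1", "TET2", "WT1", "IDH1",
             "IDH2", "NRAS", "KRAS", "PTPN11", "ASXL1", "TP53", "CEBPA",
             "SRSF2", "U2AF1", "STAG2", "BCOR", "GATA2", "KIT"),
    weight = c(10, 9, 9, 6, 6, 5, 4, 4, 4, 3, 3, 3, 3, 2, 2, 2, 2, 2, 1, 1)
  )
}

#' Simulate a diagnosis/relapse mutation meta-cohort
#'
#' Draws a clonal bin per patient, plants 1-8 mutations whose VAF pairs
#' force the intended gained/lost/stable calls under the 0.05/0.10 rule,
#' and attaches clinical covariates with exponential relapse times whose
#' hazard is `hr_stable`-fold higher for Stable patients.
#'
#' @param config An [sim_config()] object.
#' @return A list with tibbles `mutations` (patient_id, gene, variant_id,
#'   vaf_dx, vaf_rel, quantifiable, present_dx, present_rel, tier),
#'   `clinical` (patient_id, age, sex, days_to_relapse, relapse_event) and
#'   `truth` (patient_id, bin; plus per-mutation `class` on `mutations`
#'   as `true_class`).
#' @export
simulate_mutation_cohort <- function(config) {
  stopifnot(inherits(config, "epiclone_sim_config"))
  if (config$n_patients < 1) {
    abort("need at least one patient", class = "epiclone_config_error")
  }
  set.seed(offset_seed(config$seed, 101))
  bins <- names(config$bin_probabilities)
  patient_bin <- sample(bins, config$n_patients, replace = TRUE,
                        prob = config$bin_probabilities)
  panel <- aml_panel_genes()

  draw_vafs <- function(class, n) {
    dx <- numeric(n); rel <- numeric(n)
    g <- class == "gained"; l <- class == "lost"; s <- class == "stable"
    dx[g] <- runif(sum(g), 0, 0.049); rel[g] <- runif(sum(g), 0.12, 0.6)
    dx[l] <- runif(sum(l), 0.12, 0.6); rel[l] <- runif(sum(l), 0, 0.049)
    dx[s] <- runif(sum(s), 0.12, 0.6)
    rel[s] <- pmin(pmax(dx[s] + rnorm(sum(s), 0, 0.03), 0.06), 0.95)
    list(dx = dx, rel = rel)
  }

  per_patient <- lapply(seq_len(config$n_patients), function(i) {
    bin <- patient_bin[i]
    n_mut <- if (bin == "GainAndLoss") sample(2:8, 1) else sample(1:8, 1)
    class <- rep("stable", n_mut)
    if (bin == "Gain") class[1] <- "gained"
    if (bin == "Loss") class[1] <- "lost"
    if (bin == "GainAndLoss") class[1:2] <- c("gained", "lost")
    if (bin %in% c("Gain", "Loss") && n_mut > 1) {
      # extra dynamic mutations of the same direction keep the bin intact
      extra <- runif(n_mut - 1) < 0.2
      class[-1][extra] <- if (bin == "Gain") "gained" else "lost"
    }
    genes <- sample(panel$gene, n_mut, replace = TRUE, prob = panel$weight)
    v <- draw_vafs(class, n_mut)
    # a minority of FLT3/NPM1 events are non-quantifiable indels tracked by
    # presence calls only
    quantifiable <- !(genes %in% c("FLT3", "NPM1") & runif(n_mut) < 0.25)
    present_dx <- ifelse(quantifiable, NA, class != "gained")
    present_rel <- ifelse(quantifiable, NA, class != "lost")
    tibble(
      patient_id = sprintf("P%03d", i),
      gene = genes,
      variant_id = sprintf("P%03d_v%d", i, seq_len(n_mut)),
      vaf_dx = ifelse(quantifiable, v$dx, NA_real_),
      vaf_rel = ifelse(quantifiable, v$rel, NA_real_),
      quantifiable = quantifiable,
      present_dx = present_dx,
      present_rel = present_rel,
      tier = sample(1:2, n_mut, replace = TRUE, prob = c(0.7, 0.3)),
      true_class = class
    )
  })
  mutations <- dplyr::bind_rows(per_patient)

  stable <- patient_bin == "Stable"
  base_rate <- log(2) / 300  # median ~300 days to relapse for Unstable
  rate <- base_rate * ifelse(stable, config$hr_stable, 1)
  time <- rexp(config$n_patients, rate)
  censored <- runif(config$n_patients) < config$censor_prob
  obs <- ifelse(censored, time * runif(config$n_patients), time)
  clinical <- tibble(
    patient_id = sprintf("P%03d", seq_len(config$n_patients)),
    age = round(pmin(pmax(rnorm(config$n_patients, 60, 10), 18), 90)),
    sex = sample(c("F", "M"), config$n_patients, replace = TRUE),
    days_to_relapse = ceiling(obs),
    relapse_event = !censored
  )
  list(
    mutations = mutations,
    clinical = clinical,
    truth = tibble(patient_id = clinical$patient_id, bin = patient_bin)
  )
}

#' Simulate a bulk diagnosis/relapse ATAC cohort
#'
#' Negative-binomial Tn5 cut-site counts over fixed-width 500-bp peaks for
#' `n_bulk_patients` patients at two timepoints with technical replicates.
#' A planted signature of `signature_size` peaks is shifted by
#' `effect_log2fc` at relapse in every patient.
#'
#' @param config An [sim_config()] object.
#' @param signature_layout `"random"` scatters the signature over the peak
#'   set; `"block"` places it in one contiguous genomic block (for locus
#'   scans).
#' @return List with `counts` (peaks x samples, dense integer matrix),
#'   `peaks` (chrom/start/end/name), `samples` metadata tibble and `truth`
#'   (signature peak names, direction, effect).
#' @export
simulate_bulk_chromatin_cohort <- function(config,
                                           signature_layout = c("random", "block")) {
  stopifnot(inherits(config, "epiclone_sim_config"))
  signature_layout <- match.arg(signature_layout)
  set.seed(offset_seed(config$seed, 202))

  n_peaks <- config$n_peaks
  peaks <- tibble(
    chrom = "chr1",
    start = seq(0L, by = 2000L, length.out = n_peaks),
    name = sprintf("peak_%05d", seq_len(n_peaks))
  )
  peaks$end <- peaks$start + 500L

  sig_idx <- switch(signature_layout,
    random = sort(sample.int(n_peaks, config$signature_size)),
    block = seq(floor(n_peaks / 2) + 1, length.out = config$signature_size)
  )
  direction <- rep(1, config$signature_size)
  direction[seq_along(direction) %% 3 == 0] <- -1  # a third close at relapse

  samples <- tidyr::expand_grid(
    patient_id = sprintf("B%02d", seq_len(config$n_bulk_patients)),
    timepoint = c("diagnosis", "relapse"),
    replicate = seq_len(config$bulk_replicates)
  )
  samples$sample_id <- with(samples, paste(patient_id, timepoint, replicate,
                                           sep = "_"))
  samples$population <- "blast"

  log_base <- rnorm(n_peaks, log(config$mean_peak_count), 1)
  patient_eff <- matrix(rnorm(n_peaks * config$n_bulk_patients, 0, 0.25),
                        n_peaks)
  colnames(patient_eff) <- unique(samples$patient_id)
  shift <- numeric(n_peaks)
  shift[sig_idx] <- direction * config$effect_log2fc * log(2)

  counts <- matrix(0L, n_peaks, nrow(samples),
                   dimnames = list(peaks$name, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu <- exp(log_base + patient_eff[, samples$patient_id[j]] +
                if (samples$timepoint[j] == "relapse") shift else 0)
    mu <- mu * exp(rnorm(1, 0, 0.1))  # library-depth wobble per replicate
    counts[, j] <- rnbinom(n_peaks, mu = mu, size = 1 / config$nb_dispersion)
  }

  list(
    counts = counts, peaks = peaks, samples = samples,
    truth = {
      signed_lfc <- direction * config$effect_log2fc
      tibble(
        peak = peaks$name[sig_idx],
        direction = ifelse(direction > 0, "up", "down"),
        log2fc = signed_lfc
      )
    }
  )
}

#' Simulate a healthy hematopoietic single-cell reference
#'
#' Each cell type receives a private block of enriched peaks on top of a
#' shared housekeeping block; a parent type additionally borrows part of
#' each child's block so the hierarchy produces graded similarity.
#'
#' @param config An [sim_config()] object.
#' @param depth Expected fragments per cell.
#' @return List with `counts` (peaks x cells sparse), `cells`
#'   (cell, celltype) and `peaks`.
#' @export
simulate_reference_hematopoiesis <- function(config, depth = 3000) {
  stopifnot(inherits(config, "epiclone_sim_config"))
  ct <- config$celltypes
  if (nrow(ct) < 1) abort("need at least one cell type",
                          class = "epiclone_config_error")
  set.seed(offset_seed(config$seed, 303))

  n_types <- nrow(ct)
  n_peaks <- config$n_ref_peaks
  n_house <- floor(n_peaks * 0.3)
  block <- floor((n_peaks - n_house) / n_types)

  weight <- matrix(0.05, n_peaks, n_types,
                   dimnames = list(sprintf("refpeak_%04d", seq_len(n_peaks)),
                                   ct$celltype))
  weight[seq_len(n_house), ] <- 1
  block_of <- function(i) n_house + (i - 1L) * block + seq_len(block)
  for (i in seq_len(n_types)) weight[block_of(i), i] <- 4
  for (i in seq_len(n_types)) {
    kids <- which(ct$parent == ct$celltype[i])
    for (k in kids) weight[block_of(k), i] <- weight[block_of(k), i] + 1.5
  }

  cells <- tibble(
    cell = sprintf("ref_%s_%03d", rep(ct$celltype, each = config$cells_per_type),
                   rep(seq_len(config$cells_per_type), n_types)),
    celltype = rep(ct$celltype, each = config$cells_per_type)
  )
  prob <- sweep(weight, 2, colSums(weight), "/")
  counts_list <- lapply(seq_len(nrow(cells)), function(i) {
    p <- prob[, cells$celltype[i]]
    d <- rpois(1, depth)
    tab <- tabulate(sample.int(n_peaks, d, replace = TRUE, prob = p), n_peaks)
    Matrix::sparseMatrix(i = which(tab > 0), j = rep(1L, sum(tab > 0)),
                         x = tab[tab > 0], dims = c(n_peaks, 1L))
  })
  counts <- do.call(cbind, counts_list)
  dimnames(counts) <- list(rownames(weight), cells$cell)
  peaks <- tibble(
    chrom = "chrR", start = seq(0L, by = 1000L, length.out = n_peaks),
    end = seq(0L, by = 1000L, length.out = n_peaks) + 500L,
    name = rownames(weight)
  )
  list(counts = counts, cells = cells, peaks = peaks,
       truth = list(weight = weight))
}

# Validate a clone tree spec: known parents, acyclic, inherited variants.
validate_clone_tree <- function(spec) {
  check_columns(spec, c("clone", "parent", "variants", "freq_dx", "freq_rel"))
  roots <- which(is.na(spec$parent))
  if (length(roots) < 1) {
    abort("clone tree must have a root (parent NA)",
          class = "epiclone_config_error")
  }
  for (i in seq_len(nrow(spec))) {
    seen <- character(0)
    j <- i
    while (!is.na(spec$parent[j])) {
      if (spec$clone[j] %in% seen) {
        abort("clone tree contains a cycle", class = "epiclone_config_error")
      }
      seen <- c(seen, spec$clone[j])
      j <- match(spec$parent[j], spec$clone)
      if (is.na(j)) abort("clone parent not found",
                          class = "epiclone_config_error")
    }
    p <- match(spec$parent[i], spec$clone)
    if (!is.na(p) &&
        !all(spec$variants[[p]] %in% spec$variants[[i]])) {
      abort("child clones must inherit the parent's defining variants",
            class = "epiclone_config_error")
    }
  }
  invisible(spec)
}

#' Simulate mitochondrial scATAC allele counts with a planted clone tree
#'
#' Cells are assigned to clones by the per-timepoint frequencies of
#' `clone_tree_spec`; per-variant alt read counts are binomial at the
#' clone's planted heteroplasmy given Poisson coverage, with a symmetric
#' 50/50 strand split. Artifact variants get a per-cell skewed strand split
#' so the strand-correlation filter removes them. Clone-specific chromatin
#' programs are planted in a parallel peak-count matrix; `convergence`
#' `"on"` moves every clone's relapse profile toward one shared relapse
#' state, `"off"` keeps clone profiles stationary across timepoints.
#'
#' @param config An [sim_config()] object.
#' @param convergence `"off"` (stationary clones) or `"on"`.
#' @param convergence_weight Mixing weight toward the shared relapse profile
#'   when convergence is on.
#' @param n_mito_peaks,cell_depth Chromatin matrix size and per-cell depth.
#' @return List with strand-split allele count matrices (`alt_fw`,
#'   `alt_rev`, `ref_fw`, `ref_rev`; variants x cells), `peak_counts`
#'   (peaks x cells sparse), `cells` (cell, true_clone, timepoint),
#'   `variants` (variant, artifact flag), and the validated `tree`.
#' @export
simulate_mito_scatac <- function(config, convergence = c("off", "on"),
                                 convergence_weight = 0.7,
                                 n_mito_peaks = 2000L, cell_depth = 2000) {
  stopifnot(inherits(config, "epiclone_sim_config"))
  convergence <- match.arg(convergence)
  tree <- validate_clone_tree(config$clone_tree_spec)
  set.seed(offset_seed(config$seed, 404))

  real_variants <- unique(unlist(tree$variants))
  artifacts <- if (config$n_artifact_variants > 0) {
    sprintf("art%d_bias", seq_len(config$n_artifact_variants))
  } else character(0)
  variants <- c(real_variants, artifacts)
  n_var <- length(variants)

  assign_cells <- function(tp, freq) {
    tibble(
      cell = sprintf("%s_cell_%04d", tp, seq_len(config$n_mito_cells)),
      true_clone = sample(tree$clone, config$n_mito_cells, replace = TRUE,
                          prob = freq),
      timepoint = tp
    )
  }
  cells <- dplyr::bind_rows(assign_cells("diagnosis", tree$freq_dx),
                            assign_cells("relapse", tree$freq_rel))
  n_cells <- nrow(cells)

  # planted heteroplasmy per (variant, clone)
  het <- matrix(0, n_var, nrow(tree), dimnames = list(variants, tree$clone))
  for (k in seq_len(nrow(tree))) het[tree$variants[[k]], k] <- config$heteroplasmy

  # per-cell mito depth factor shared between strands: strand coverages of a
  # cell rise and fall together, as in real libraries, which is what makes
  # genuine variants strand-concordant
  depth_factor <- exp(rnorm(n_cells, 0, 0.6))
  lambda <- outer(rep(config$mean_mito_coverage / 2, n_var), depth_factor)
  cov_fw <- matrix(rpois(n_var * n_cells, lambda), n_var)
  cov_rev <- matrix(rpois(n_var * n_cells, lambda), n_var)

  p <- het[, cells$true_clone, drop = FALSE]
  p_fw <- p; p_rev <- p
  if (length(artifacts) > 0) {
    # artifacts: moderate apparent heteroplasmy whose reads sit on one
    # strand per cell, destroying the across-strand correlation
    skew <- matrix(stats::rbeta(length(artifacts) * n_cells, 0.1, 0.1),
                   length(artifacts))
    p_fw[artifacts, ] <- pmin(1, 2 * 0.3 * skew)
    p_rev[artifacts, ] <- pmin(1, 2 * 0.3 * (1 - skew))
  }
  alt_fw <- matrix(rbinom(n_var * n_cells, cov_fw, p_fw), n_var)
  alt_rev <- matrix(rbinom(n_var * n_cells, cov_rev, p_rev), n_var)
  ref_fw <- cov_fw - alt_fw
  ref_rev <- cov_rev - alt_rev
  dn <- list(variants, cells$cell)
  dimnames(alt_fw) <- dimnames(alt_rev) <- dn
  dimnames(ref_fw) <- dimnames(ref_rev) <- dn

  # clone chromatin programs
  base <- rnorm(n_mito_peaks, 0, 1)
  program <- sapply(seq_len(nrow(tree)), function(k) {
    idx <- sample.int(n_mito_peaks, floor(n_mito_peaks * 0.1))
    prof <- base
    prof[idx] <- prof[idx] + rnorm(length(idx), 0, 1.5)
    prof
  })
  colnames(program) <- tree$clone
  shared_rel <- base + {
    idx <- sample.int(n_mito_peaks, floor(n_mito_peaks * 0.1))
    d <- numeric(n_mito_peaks); d[idx] <- rnorm(length(idx), 0, 1.5); d
  }
  profile_for <- function(clone, tp) {
    if (tp == "relapse" && convergence == "on") {
      (1 - convergence_weight) * program[, clone] +
        convergence_weight * shared_rel
    } else {
      program[, clone]
    }
  }
  peak_names <- sprintf("mpeak_%04d", seq_len(n_mito_peaks))
  cols <- lapply(seq_len(n_cells), function(i) {
    w <- exp(profile_for(cells$true_clone[i], cells$timepoint[i]))
    tab <- tabulate(sample.int(n_mito_peaks, rpois(1, cell_depth),
                               replace = TRUE, prob = w / sum(w)),
                    n_mito_peaks)
    nz <- which(tab > 0)
    Matrix::sparseMatrix(i = nz, j = rep(1L, length(nz)), x = tab[nz],
                         dims = c(n_mito_peaks, 1L))
  })
  peak_counts <- do.call(cbind, cols)
  dimnames(peak_counts) <- list(peak_names, cells$cell)

  list(
    alt_fw = alt_fw, alt_rev = alt_rev, ref_fw = ref_fw, ref_rev = ref_rev,
    peak_counts = peak_counts, cells = cells,
    variants = tibble(variant = variants,
                      artifact = variants %in% artifacts),
    tree = tree
  )
}

#' Simulate an ATAC fragments table concentrated in peaks
#'
#' Convenience generator for cut-site level operations: fragments fall
#' inside randomly chosen peaks with uniform starts and 50-300 bp lengths.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`).
#' @param n_fragments Number of fragments.
#' @param barcode Barcode label recycled over fragments.
#' @param seed Integer seed.
#' @param weights Per-peak sampling weights; default log-normal draws so
#'   peaks differ in accessibility as real peaks do.
#' @return A fragments tibble (`chrom`, `start`, `end`, `barcode`, `count`).
#' @export
simulate_fragments <- function(peaks, n_fragments, barcode = "sample1",
                               seed = 1L, weights = NULL) {
  set.seed(offset_seed(seed, 505))
  if (is.null(weights)) weights <- exp(rnorm(nrow(peaks), 0, 1))
  idx <- sample.int(nrow(peaks), n_fragments, replace = TRUE,
                    prob = weights)
  start <- peaks$start[idx] +
    floor(runif(n_fragments, 0, pmax(peaks$end[idx] - peaks$start[idx] - 50, 1)))
  len <- sample(50:300, n_fragments, replace = TRUE)
  tibble(
    chrom = peaks$chrom[idx], start = as.integer(start),
    end = as.integer(start + len),
    barcode = rep_len(barcode, n_fragments), count = 1L
  )
}
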