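# Mitochondrial variant QC, heteroplasmy, mitoclone clustering, clone tree
# reconstruction from variant containment, clone frequency dynamics, and
# the convergent-epigenetic-evolution test.

#' Per-variant heteroplasmy and QC statistics
#'
#' Heteroplasmy is `alt / (alt + ref)` per cell, missing where coverage is
#' zero. Per-variant strand correlation is the Pearson correlation of alt
#' read counts between the forward and reverse strands, computed over
#' cells with at least one read on each strand.
#'
#' @param alt_fw,alt_rev,ref_fw,ref_rev Variants x cells integer matrices
#'   of strand-split allele counts, identical dimnames.
#' @return List with `heteroplasmy` (variants x cells, `NA` at zero
#'   coverage) and `stats` tibble (`variant`, `n_cells_detected`,
#'   `strand_correlation`, `mean_coverage`).
#' @export
compute_heteroplasmy <- function(alt_fw, alt_rev, ref_fw, ref_rev) {
  stopifnot(all(dim(alt_fw) == dim(alt_rev)),
            all(dim(alt_fw) == dim(ref_fw)),
            all(dim(alt_fw) == dim(ref_rev)))
  alt <- alt_fw + alt_rev
  cov <- alt + ref_fw + ref_rev
  het <- alt / cov
  het[cov == 0] <- NA

  stats_tbl <- dplyr::bind_rows(lapply(seq_len(nrow(alt)), function(v) {
    fw_reads <- alt_fw[v, ] + ref_fw[v, ]
    rev_reads <- alt_rev[v, ] + ref_rev[v, ]
    use <- fw_reads >= 1 & rev_reads >= 1
    sc <- if (sum(use) >= 3 && sd(alt_fw[v, use]) > 0 &&
                sd(alt_rev[v, use]) > 0) {
      cor(alt_fw[v, use], alt_rev[v, use])
    } else NA_real_
    tibble(
      variant = rownames(alt)[v] %||% sprintf("var_%d", v),
      n_cells_detected = sum(alt[v, ] > 0),
      strand_correlation = sc,
      mean_coverage = mean(cov[v, ])
    )
  }))
  list(heteroplasmy = het, stats = stats_tbl)
}

#' Filter mitochondrial variants on detection, strand balance and coverage
#'
#' Keeps variants detected in more than `min_cells` cells, with strand
#' correlation above `min_strand_cor` and mean coverage above
#' `min_coverage` — all strict inequalities. Variants whose strand
#' correlation could not be computed fail the filter.
#'
#' @param stats Stats tibble from [compute_heteroplasmy()].
#' @param min_cells,min_strand_cor,min_coverage Thresholds; defaults 3,
#'   0.65 and 10.
#' @return The passing rows of `stats`.
#' @export
filter_mito_variants <- function(stats, min_cells = 3, min_strand_cor = 0.65,
                                 min_coverage = 10) {
  check_columns(stats, c("variant", "n_cells_detected", "strand_correlation",
                         "mean_coverage"))
  dplyr::filter(stats,
                .data$n_cells_detected > min_cells,
                !is.na(.data$strand_correlation),
                .data$strand_correlation > min_strand_cor,
                .data$mean_coverage > min_coverage)
}

#' Cluster cells into mitoclones from a heteroplasmy matrix
#'
#' The variant x cell heteroplasmy matrix is binarized at
#' `binarize_threshold` (missing values count as absent), and cells are
#' clustered on the binary profiles with a shared-nearest-neighbour graph
#' and Louvain modularity at the given resolution. Mean heteroplasmy per
#' (variant, cluster) is reported so clusters driven by low-heteroplasmy
#' variants can be flagged (`low_het_flag`: the cluster's top defining
#' variant has mean heteroplasmy below 0.1).
#'
#' @param heteroplasmy Variants x cells matrix (typically restricted to
#'   variants passing [filter_mito_variants()]).
#' @param cell_meta Optional tibble with `cell` (+ `timepoint`).
#' @param binarize_threshold Variant-positive cutoff (default 0.1).
#' @param resolution Louvain resolution; the paper selects this manually —
#'   see [sweep_mitoclone_resolution()].
#' @param k SNN neighbours (default 20).
#' @param seed Integer seed.
#' @return Object of class `epiclone_mitoclones`: `assignments` tibble
#'   (`cell`, `clone`, metadata), `cluster_het` (variant x clone mean
#'   heteroplasmy), `flags` tibble.
#' @export
cluster_mitoclones <- function(heteroplasmy, cell_meta = NULL,
                               binarize_threshold = 0.1, resolution = 1,
                               k = 20, seed = 1L) {
  bin <- (!is.na(heteroplasmy)) & heteroplasmy >= binarize_threshold
  storage.mode(bin) <- "double"
  if (all(bin == 0)) {
    warn("all-zero binarized matrix; returning a single clone")
    cl <- rep(1L, ncol(heteroplasmy))
  } else {
    cl <- snn_cluster(t(bin), k = k, resolution = resolution, seed = seed)
  }
  assignments <- tibble(
    cell = colnames(heteroplasmy) %||% sprintf("cell_%d", seq_along(cl)),
    clone = cl
  )
  if (!is.null(cell_meta)) {
    assignments <- dplyr::left_join(assignments, cell_meta, by = "cell")
  }
  ids <- sort(unique(cl))
  cluster_het <- sapply(ids, function(g) {
    rowMeans(heteroplasmy[, cl == g, drop = FALSE], na.rm = TRUE)
  })
  if (is.null(dim(cluster_het))) {
    cluster_het <- matrix(cluster_het, ncol = length(ids))
    rownames(cluster_het) <- rownames(heteroplasmy)
  }
  colnames(cluster_het) <- paste0("clone", ids)
  flags <- tibble(
    clone = ids,
    top_variant = rownames(cluster_het)[apply(cluster_het, 2, which.max)],
    top_het = apply(cluster_het, 2, max),
    low_het_flag = apply(cluster_het, 2, max) < 0.1
  )
  structure(list(assignments = assignments, cluster_het = cluster_het,
                 flags = flags),
            class = "epiclone_mitoclones")
}

#' @export
print.epiclone_mitoclones <- function(x, ...) {
  cat(sprintf("Mitoclones: %d clones over %d cells\n",
              ncol(x$cluster_het), nrow(x$assignments)))
  invisible(x)
}

#' Sweep clustering resolutions
#'
#' Companion to [cluster_mitoclones()] for the manual resolution choice:
#' reports the number of clones found per resolution.
#'
#' @inheritParams cluster_mitoclones
#' @param resolutions Numeric vector to sweep.
#' @return Tibble with `resolution`, `n_clones`.
#' @export
sweep_mitoclone_resolution <- function(heteroplasmy,
                                       resolutions = c(0.1, 0.25, 0.5, 1, 2),
                                       binarize_threshold = 0.1, k = 20,
                                       seed = 1L) {
  dplyr::bind_rows(lapply(resolutions, function(r) {
    fit <- cluster_mitoclones(heteroplasmy,
                              binarize_threshold = binarize_threshold,
                              resolution = r, k = k, seed = seed)
    tibble(resolution = r, n_clones = ncol(fit$cluster_het))
  }))
}

#' Infer the clone hierarchy from shared and exclusive variants
#'
#' A variant is *present* in a clone when its mean heteroplasmy reaches
#' `presence_threshold`. Variants present in every clone form the root
#' edge; containment of presence sets defines descent (a clone whose set
#' strictly contains another's descends from it, attached to the largest
#' such set). Non-nesting conflicts are reported and may be resolved by a
#' manual override edge table, mirroring the manual curation this step
#' receives in practice.
#'
#' @param cluster_het Variants x clones mean-heteroplasmy matrix (from
#'   [cluster_mitoclones()]).
#' @param presence_threshold Default 0.2.
#' @param overrides Optional tibble (`clone`, `parent`) forcing edges.
#' @return Object of class `epiclone_clone_tree`: `edges` tibble
#'   (`clone`, `parent`), `defining` list of variant sets, `root_variants`,
#'   `conflicts` tibble.
#' @export
infer_clone_tree <- function(cluster_het, presence_threshold = 0.2,
                             overrides = NULL) {
  presence <- cluster_het >= presence_threshold
  clones <- colnames(cluster_het)
  sets <- lapply(clones, function(cl) rownames(cluster_het)[presence[, cl]])
  names(sets) <- clones
  root_variants <- Reduce(intersect, sets)

  sizes <- lengths(sets)
  conflicts <- list()
  parent <- setNames(rep(NA_character_, length(clones)), clones)
  for (cl in clones) {
    anc <- Filter(function(other) {
      other != cl && all(sets[[other]] %in% sets[[cl]]) &&
        sizes[other] < sizes[cl]
    }, clones)
    if (length(anc) == 0) next
    best <- anc[which.max(sizes[anc])]
    # all candidate ancestors must themselves nest; otherwise report
    top <- anc[sizes[anc] == sizes[best]]
    if (length(top) > 1) {
      conflicts[[length(conflicts) + 1]] <-
        tibble(clone = cl, candidates = paste(top, collapse = ","))
      best <- sort(top)[1]
    }
    parent[cl] <- best
  }
  if (!is.null(overrides)) {
    check_columns(overrides, c("clone", "parent"))
    parent[overrides$clone] <- overrides$parent
  }
  structure(
    list(edges = tibble(clone = clones, parent = unname(parent[clones])),
         defining = sets, root_variants = root_variants,
         conflicts = dplyr::bind_rows(conflicts)),
    class = "epiclone_clone_tree"
  )
}

#' @export
print.epiclone_clone_tree <- function(x, ...) {
  cat("Clone tree:\n")
  for (i in seq_len(nrow(x$edges))) {
    cat(sprintf("  %s <- %s  {%s}\n", x$edges$clone[i],
                x$edges$parent[i] %||% "(root)",
                paste(x$defining[[x$edges$clone[i]]], collapse = ",")))
  }
  if (nrow(x$conflicts) > 0) cat(sprintf("  %d containment conflict(s)\n",
                                         nrow(x$conflicts)))
  invisible(x)
}

#' Clone frequencies per timepoint with expansion tests
#'
#' Clone fractions per timepoint (fishplot-ready), with a two-proportion
#' z-test (continuity corrected) per clone flagging significant expansion
#' or contraction between diagnosis and relapse.
#'
#' @param assignments Tibble with `cell`, `clone`, `timepoint`.
#' @param alpha Significance level for the flag (default 0.05).
#' @return Tibble per clone: `freq_diagnosis`, `freq_relapse`, counts,
#'   `p`, `significant`, `direction`.
#' @export
clone_frequencies <- function(assignments, alpha = 0.05) {
  check_columns(assignments, c("cell", "clone", "timepoint"))
  tps <- c("diagnosis", "relapse")
  n_tp <- table(factor(assignments$timepoint, levels = tps))
  if (any(n_tp == 0)) {
    abort("both timepoints need at least one cell",
          class = "epiclone_validation_error")
  }
  tab <- table(factor(assignments$clone),
               factor(assignments$timepoint, levels = tps))
  dplyr::bind_rows(lapply(rownames(tab), function(cl) {
    k <- tab[cl, ]
    ptest <- suppressWarnings(
      prop.test(k, as.vector(n_tp), correct = TRUE))
    tibble(
      clone = cl,
      n_diagnosis = unname(k[1]), n_relapse = unname(k[2]),
      freq_diagnosis = unname(k[1] / n_tp[1]),
      freq_relapse = unname(k[2] / n_tp[2]),
      p = ptest$p.value,
      significant = ptest$p.value < alpha,
      direction = dplyr::case_when(
        k[2] / n_tp[2] > k[1] / n_tp[1] ~ "expansion",
        k[2] / n_tp[2] < k[1] / n_tp[1] ~ "contraction",
        TRUE ~ "stable")
    )
  }))
}

#' Test for convergent epigenetic evolution between clones
#'
#' Per (timepoint, clone), a pseudobulk profile is the CPM-normalized sum
#' of peak counts; within each timepoint all off-diagonal clone-pair
#' Pearson correlations are collected, and the diagnosis and relapse
#' collections are compared with an unpaired two-sample t-test.
#' Convergence is declared when the relapse mean exceeds the diagnosis
#' mean at `p < alpha`.
#'
#' @param assignments Tibble with `cell`, `clone`, `timepoint`.
#' @param counts Peaks x cells matrix.
#' @param alpha Significance level (default 0.05).
#' @param min_cells Clones with fewer cells at a timepoint are excluded
#'   from that timepoint (default 5).
#' @return Object of class `epiclone_convergence`: `similarity` (tibble of
#'   within-timepoint clone-pair correlations), per-timepoint matrices,
#'   `mean_dx`, `mean_rel`, `t`, `p`, `convergent`.
#' @export
convergence_analysis <- function(assignments, counts, alpha = 0.05,
                                 min_cells = 5) {
  check_columns(assignments, c("cell", "clone", "timepoint"))
  sims <- lapply(c("diagnosis", "relapse"), function(tp) {
    a <- assignments[assignments$timepoint == tp, ]
    keep <- names(which(table(a$clone) >= min_cells))
    if (length(keep) < 2) {
      abort(sprintf("similarity undefined at %s: fewer than two clones", tp),
            class = "epiclone_validation_error")
    }
    pb <- sapply(keep, function(cl) {
      Matrix::rowSums(counts[, a$cell[a$clone == cl], drop = FALSE])
    })
    if (any(colSums(pb) == 0)) {
      abort("zero-count clone pseudobulk", class = "epiclone_validation_error")
    }
    sim <- stats::cor(as.matrix(cpm_normalize(pb)))
    list(matrix = sim,
         values = tibble(timepoint = tp, r = sim[upper.tri(sim)]))
  })
  values <- dplyr::bind_rows(sims[[1]]$values, sims[[2]]$values)
  dx <- values$r[values$timepoint == "diagnosis"]
  rel <- values$r[values$timepoint == "relapse"]
  if (sd(values$r) == 0) {
    abort("t-test undefined: zero variance in inter-clone similarities",
          class = "epiclone_zero_variance")
  }
  tt <- t.test(rel, dx, var.equal = FALSE)
  structure(
    list(similarity = values,
         matrix_diagnosis = sims[[1]]$matrix,
         matrix_relapse = sims[[2]]$matrix,
         mean_dx = mean(dx), mean_rel = mean(rel),
         t = unname(tt$statistic), p = tt$p.value,
         convergent = mean(rel) > mean(dx) && tt$p.value < alpha),
    class = "epiclone_convergence"
  )
}

#' @export
print.epiclone_convergence <- function(x, ...) {
  cat("Inter-clone epigenetic similarity (pseudobulk Pearson)\n")
  cat(sprintf("  diagnosis mean r = %.3f, relapse mean r = %.3f\n",
              x$mean_dx, x$mean_rel))
  cat(sprintf("  unpaired t = %.2f, p = %.4g -> %sconvergent\n",
              x$t, x$p, if (x$convergent) "" else "not "))
  invisible(x)
}

#' Concordance of per-clone accessibility shifts at relapse
#'
#' Per clone present at both timepoints, the per-feature shift vector is
#' `log2((CPM_rel + 1) / (CPM_dx + 1))`; pairwise Pearson correlations
#' between clones' shift vectors measure whether distinct clones moved the
#' same way (convergent shifts).
#'
#' @param assignments Tibble with `cell`, `clone`, `timepoint`.
#' @param counts Peaks x cells matrix.
#' @param min_cells Minimum cells per (clone, timepoint) (default 5).
#' @return List with `correlation` (clone x clone matrix) and `shifts`
#'   (feature x clone matrix). Clones absent at a timepoint are excluded
#'   with a message; a zero-variance shift vector raises an error.
#' @export
clone_shift_concordance <- function(assignments, counts, min_cells = 5) {
  check_columns(assignments, c("cell", "clone", "timepoint"))
  tab <- table(assignments$clone, assignments$timepoint)
  ok <- rownames(tab)[tab[, "diagnosis"] >= min_cells &
                        tab[, "relapse"] >= min_cells]
  dropped <- setdiff(rownames(tab), ok)
  if (length(dropped) > 0) {
    inform(sprintf("clone(s) %s absent at a timepoint; excluded",
                   paste(dropped, collapse = ", ")))
  }
  if (length(ok) < 2) {
    abort("need two clones present at both timepoints",
          class = "epiclone_validation_error")
  }
  shift_of <- function(cl) {
    pb <- sapply(c("diagnosis", "relapse"), function(tp) {
      cells <- assignments$cell[assignments$clone == cl &
                                  assignments$timepoint == tp]
      Matrix::rowSums(counts[, cells, drop = FALSE])
    })
    pb <- as.matrix(cpm_normalize(pb))
    log2((pb[, "relapse"] + 1) / (pb[, "diagnosis"] + 1))
  }
  shifts <- sapply(ok, shift_of)
  if (any(apply(shifts, 2, sd) == 0)) {
    abort("shift correlation undefined: zero-variance shift vector",
          class = "epiclone_zero_variance")
  }
  list(correlation = stats::cor(shifts), shifts = shifts)
}
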