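# Differential accessibility between timepoints with patient covariates,
# and the locus-level window scan over differential results.

#' Differential accessibility between diagnosis and relapse
#'
#' Per-feature negative-binomial GLM with a timepoint effect and patient
#' fixed effects, median-of-ratios size factors, empirical-Bayes dispersion
#' shrinkage toward a mean-dispersion trend, Wald test on the timepoint
#' coefficient and Benjamini-Hochberg adjustment — the DESeq2 model, run
#' with default parameters. Features with all-zero counts are excluded from
#' testing and reported with `NA` statistics.
#'
#' @param counts Integer matrix, features x samples, columns named by
#'   sample id.
#' @param samples Sample metadata with `sample_id`, `patient_id`,
#'   `timepoint` (`diagnosis`/`relapse`).
#' @return Tibble with `feature`, `base_mean`, `log2fc` (relapse vs
#'   diagnosis), `p`, `padj`.
#' @export
differential_accessibility <- function(counts, samples) {
  check_columns(samples, c("sample_id", "patient_id", "timepoint"))
  stopifnot(all(samples$sample_id %in% colnames(counts)))
  if (dplyr::n_distinct(samples$patient_id[samples$timepoint == "diagnosis"]) < 2) {
    abort("need at least two patients with both timepoints",
          class = "epiclone_validation_error")
  }
  m <- as.matrix(counts[, samples$sample_id, drop = FALSE])
  storage.mode(m) <- "integer"
  feature_names <- rownames(m) %||% sprintf("feature_%d", seq_len(nrow(m)))
  nonzero <- rowSums(m) > 0

  col_data <- S4Vectors::DataFrame(
    patient_id = factor(samples$patient_id),
    timepoint = factor(samples$timepoint, levels = c("diagnosis", "relapse"))
  )
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = m[nonzero, , drop = FALSE],
    colData = col_data,
    design = ~ patient_id + timepoint
  )
  dds <- tryCatch(
    DESeq2::DESeq(dds, quiet = TRUE),
    error = function(e) {
      # degenerate inputs (near-constant gene-wise dispersion) have no
      # usable mean-dispersion trend; fall back to the gene-wise estimates
      dds <- DESeq2::estimateSizeFactors(dds)
      dds <- DESeq2::estimateDispersionsGeneEst(dds)
      DESeq2::dispersions(dds) <- S4Vectors::mcols(dds)$dispGeneEst
      DESeq2::nbinomWaldTest(dds)
    })
  res <- DESeq2::results(dds, contrast = c("timepoint", "relapse", "diagnosis"))

  out <- tibble(
    feature = feature_names,
    base_mean = NA_real_, log2fc = NA_real_, p = NA_real_, padj = NA_real_
  )
  out$base_mean[nonzero] <- res$baseMean
  out$log2fc[nonzero] <- res$log2FoldChange
  out$p[nonzero] <- res$pvalue
  out$padj[nonzero] <- res$padj
  out
}

#' Scan the genome for windows enriched in differential peaks
#'
#' Slides windows along each chromosome and tests, per direction, whether
#' the in-window count of significantly enriched (or depleted) peaks
#' exceeds the genome-wide significant fraction, by a one-sided binomial
#' test with BH adjustment. Windows holding fewer than `min_peaks` peaks
#' are skipped.
#'
#' @param differential Output of [differential_accessibility()].
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `name` matching
#'   `differential$feature`).
#' @param window_bp,step_bp Window geometry (defaults 100 kb / 50 kb).
#' @param alpha Significance cutoff on `padj` for calling a peak
#'   differential (default 0.05).
#' @param min_peaks Minimum peaks per evaluated window.
#' @return Tibble per (window, direction): `chrom`, `start`, `end`,
#'   `n_peaks`, `n_signif`, `global_rate`, `p`, `padj`, `flagged`.
#' @export
locus_window_scan <- function(differential, peaks, window_bp = 1e5,
                              step_bp = 5e4, alpha = 0.05, min_peaks = 5L) {
  check_columns(peaks, c("chrom", "start", "end", "name"))
  d <- dplyr::inner_join(differential, peaks,
                         by = c(feature = "name"))
  d$mid <- (d$start + d$end) / 2
  d$sig_up <- !is.na(d$padj) & d$padj < alpha & d$log2fc > 0
  d$sig_down <- !is.na(d$padj) & d$padj < alpha & d$log2fc < 0

  scan_direction <- function(flag_col, direction) {
    global_rate <- mean(d[[flag_col]])
    rows <- lapply(unique(d$chrom), function(ch) {
      dc <- d[d$chrom == ch, ]
      last <- max(dc$end)
      starts <- seq(0, max(0, last), by = step_bp)
      out <- lapply(starts, function(w0) {
        inw <- dc$mid >= w0 & dc$mid < w0 + window_bp
        n <- sum(inw)
        if (n < min_peaks) return(NULL)
        k <- sum(dc[[flag_col]][inw])
        p <- pbinom(k - 1, n, global_rate, lower.tail = FALSE)
        tibble(chrom = ch, start = w0, end = w0 + window_bp,
               direction = direction, n_peaks = n, n_signif = k,
               global_rate = global_rate, p = p)
      })
      dplyr::bind_rows(out)
    })
    dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(scan_direction("sig_up", "enriched"),
                          scan_direction("sig_down", "depleted"))
  if (nrow(res) == 0) return(res)
  res$padj <- p.adjust(res$p, "BH")
  res$flagged <- res$padj < alpha & res$n_signif > res$n_peaks * res$global_rate
  dplyr::arrange(res, .data$direction, .data$chrom, .data$start)
}
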