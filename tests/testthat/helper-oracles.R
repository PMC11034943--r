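# Independent oracles used to cross-check the package implementations.
# These are deliberately naive (plain loops / closed forms) and share no
# code with the functions they verify.

# VAF threshold rule, re-stated from scratch.
oracle_classify <- function(vaf_dx, vaf_rel) {
  if (vaf_dx < 0.05 && vaf_rel > 0.1) return("gained")
  if (vaf_dx > 0.1 && vaf_rel < 0.05) return("lost")
  "stable"
}

# Quadratic brute-force cut-site counting: 0-based site in [start, end).
oracle_count <- function(sites, peaks) {
  out <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    n <- 0L
    for (j in seq_len(nrow(sites))) {
      if (sites$chrom[j] == peaks$chrom[i] &&
          sites$pos[j] >= peaks$start[i] && sites$pos[j] < peaks$end[i]) {
        n <- n + 1L
      }
    }
    out[i] <- n
  }
  out
}

# Iterative peak removal by explicit repeated scans.
oracle_merge <- function(peaks, min_samples = 2) {
  pool <- peaks[order(-peaks$score, peaks$chrom, peaks$start), ]
  kept <- pool[0, ]
  while (nrow(pool) > 0) {
    best <- pool[1, ]
    kept <- rbind(kept, best)
    keep_row <- logical(nrow(pool))
    for (j in seq_len(nrow(pool))) {
      keep_row[j] <- !(pool$chrom[j] == best$chrom &&
                         pool$start[j] < best$end &&
                         best$start < pool$end[j])
    }
    pool <- pool[keep_row, ]
  }
  support <- integer(nrow(kept))
  for (i in seq_len(nrow(kept))) {
    samples <- character(0)
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] == kept$chrom[i] &&
          peaks$start[j] < kept$end[i] && kept$start[i] < peaks$end[j]) {
        samples <- c(samples, peaks$sample[j])
      }
    }
    support[i] <- length(unique(samples))
  }
  kept <- kept[support >= min_samples, ]
  kept[order(kept$chrom, kept$start), ]
}

# GSEA running sum evaluated at every rank position, one step at a time.
oracle_es <- function(stat_sorted, in_set) {
  n <- length(stat_sorted)
  nh <- sum(in_set)
  w <- abs(stat_sorted[in_set])
  total <- sum(w)
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      cur <- cur + abs(stat_sorted[i]) / total
    } else {
      cur <- cur - 1 / (n - nh)
    }
    running[i] <- cur
  }
  running[which.max(abs(running))]
}

# Cosine similarity between matching rows of two matrices.
row_cosine <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    sum(a[i, ] * b[i, ]) / sqrt(sum(a[i, ]^2) * sum(b[i, ]^2))
  }, numeric(1))
}

# Small deterministic peak tibble for interval tests.
toy_peaks <- function(n = 20, chrom = "chr1", width = 500L, gap = 1500L) {
  start <- seq(0L, by = width + gap, length.out = n)
  tibble::tibble(chrom = chrom, start = start, end = start + width,
                 name = sprintf("p%03d", seq_len(n)))
}
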