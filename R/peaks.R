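# Cut-site extraction, iterative consensus peak merging, overlap counting
# and diagnosis-vs-relapse similarity for bulk ATAC data. Interval work is
# delegated to GenomicRanges/IRanges; all coordinates entering and leaving
# these functions are 0-based half-open (BED convention).

#' Convert fragments to Tn5 cut sites
#'
#' Each fragment contributes two cut sites: `start + 4` and `end - 5`
#' (0-based), the standard correction for the 9-bp Tn5 duplication.
#'
#' @param fragments Fragments tibble (`chrom`, `start`, `end`, `barcode`,
#'   `count`).
#' @param expand_duplicates If `TRUE`, a fragment with duplicate count `c`
#'   contributes its two sites `c` times each.
#' @return Tibble with `chrom`, `pos` (0-based), `barcode`.
#' @export
#' @examples
#' f <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L,
#'                     barcode = "b1", count = 1L)
#' fragments_to_cutsites(f)$pos  # 104 and 195
fragments_to_cutsites <- function(fragments, expand_duplicates = FALSE) {
  check_columns(fragments, c("chrom", "start", "end", "barcode"))
  bad <- which(!is.finite(fragments$start) | !is.finite(fragments$end) |
                 fragments$start < 0 | fragments$end <= fragments$start)
  if (length(bad) > 0) {
    abort(sprintf("malformed fragment record at line %d", bad[1]),
          class = "epiclone_validation_error")
  }
  rep_times <- if (expand_duplicates && "count" %in% names(fragments)) {
    fragments$count
  } else {
    rep(1L, nrow(fragments))
  }
  idx <- rep.int(seq_len(nrow(fragments)), rep_times)
  tibble(
    chrom = rep(fragments$chrom[idx], 2),
    pos = c(fragments$start[idx] + 4L, fragments$end[idx] - 5L),
    barcode = rep(fragments$barcode[idx], 2)
  )
}

#' Iteratively merge fixed-width peaks into a consensus set
#'
#' Peaks are ranked by descending significance score (ties broken by
#' chromosome then start for determinism); the best peak is kept and every
#' peak overlapping it discarded, repeating until none remain. Peaks
#' overlapping the blacklist are removed before ranking, and a retained
#' consensus peak must be overlapped by original calls from at least
#' `min_samples` distinct samples.
#'
#' @param peaks Tibble of 500-bp peaks: `chrom`, `start`, `end`, `score`,
#'   `sample`.
#' @param blacklist Optional tibble of excluded intervals (`chrom`,
#'   `start`, `end`).
#' @param width Required fixed peak width (default 500).
#' @param min_samples Minimum distinct samples supporting a retained peak.
#' @return Consensus peak tibble (`chrom`, `start`, `end`, `score`,
#'   `sample`, `n_samples`), pairwise non-overlapping, sorted by position.
#' @export
merge_peaks_iterative <- function(peaks, blacklist = NULL, width = 500L,
                                  min_samples = 2L) {
  check_columns(peaks, c("chrom", "start", "end", "score", "sample"))
  if (any(peaks$end - peaks$start != width)) {
    abort(sprintf("all peaks must have width %d", width),
          class = "epiclone_validation_error")
  }
  if (nrow(peaks) == 0) return(dplyr::mutate(peaks, n_samples = integer(0)))

  gr_all <- intervals_to_granges(peaks)
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    hit <- IRanges::overlapsAny(gr_all, intervals_to_granges(blacklist))
    peaks <- peaks[!hit, , drop = FALSE]
    gr_all <- gr_all[!hit]
    if (nrow(peaks) == 0) return(dplyr::mutate(peaks, n_samples = integer(0)))
  }

  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  peaks_o <- peaks[ord, , drop = FALSE]
  gr_o <- gr_all[ord]

  # Greedy sweep in rank order: a peak survives iff it overlaps no
  # higher-ranked survivor; equivalent to repeated keep-best-and-remove.
  ov <- GenomicRanges::findOverlaps(gr_o, gr_o)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  keep_pair <- q < s  # q is the higher-ranked member of each pair
  q <- q[keep_pair]; s <- s[keep_pair]
  n <- nrow(peaks_o)
  adj <- vector("list", n)
  if (length(q) > 0) {
    sp <- split(s, q)
    adj[as.integer(names(sp))] <- sp
  }
  removed <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (removed[i]) next
    if (!is.null(adj[[i]])) removed[adj[[i]]] <- TRUE
  }
  kept <- peaks_o[!removed, , drop = FALSE]

  # support: distinct samples whose original calls overlap the kept peak
  ov2 <- GenomicRanges::findOverlaps(intervals_to_granges(kept), gr_all)
  supp <- tapply(peaks$sample[S4Vectors::subjectHits(ov2)],
                 S4Vectors::queryHits(ov2),
                 function(x) length(unique(x)))
  kept$n_samples <- 0L
  kept$n_samples[as.integer(names(supp))] <- as.integer(supp)
  kept <- kept[kept$n_samples >= min_samples, , drop = FALSE]
  dplyr::arrange(as_tibble(kept), .data$chrom, .data$start)
}

#' Count cut sites in peaks
#'
#' Entry (i, j) is the number of sample-j cut sites with 0-based position
#' in the half-open interval `[start_i, end_i)`.
#'
#' @param cutsites Tibble (`chrom`, `pos`) plus a grouping column named by
#'   `sample_col` (default `barcode`).
#' @param peaks Peak tibble (`chrom`, `start`, `end`, optional `name`).
#' @param sample_col Column of `cutsites` defining matrix columns.
#' @return Integer matrix, peaks x samples, with peak names as rownames.
#' @export
count_cutsites <- function(cutsites, peaks, sample_col = "barcode") {
  check_columns(cutsites, c("chrom", "pos", sample_col))
  check_columns(peaks, c("chrom", "start", "end"))
  peak_names <- peaks$name %||% sprintf("peak_%05d", seq_len(nrow(peaks)))
  samples <- sort(unique(cutsites[[sample_col]]))
  gr_peaks <- intervals_to_granges(peaks)
  unknown <- setdiff(unique(cutsites$chrom), unique(peaks$chrom))
  if (length(unknown) > 0) {
    inform(sprintf("cut sites on chromosome(s) %s match no peak",
                   paste(unknown, collapse = ", ")))
  }
  m <- matrix(0L, nrow(peaks), length(samples),
              dimnames = list(peak_names, samples))
  for (s in samples) {
    sub <- cutsites[cutsites[[sample_col]] == s, ]
    gr_sites <- positions_to_granges(sub$chrom, sub$pos)
    m[, s] <- GenomicRanges::countOverlaps(gr_peaks, gr_sites)
  }
  m
}

#' Diagnosis vs relapse chromatin similarity per patient
#'
#' Per replicate, peak counts are CPM-normalized; replicate CPM vectors are
#' averaged per (patient, timepoint); the Pearson product-moment
#' correlation across all peaks between the two timepoint vectors is the
#' patient's similarity. Also applicable to other sample pairings (e.g.
#' LSC vs non-LSC) via `level_a`/`level_b` on another metadata column.
#'
#' @param counts Peaks x samples count matrix (columns named by sample id).
#' @param samples Sample metadata tibble with `sample_id`, `patient_id`,
#'   and the comparison column.
#' @param compare_col Metadata column defining the two states (default
#'   `timepoint`).
#' @param level_a,level_b The two states to correlate.
#' @return Tibble with `patient_id` and `r`.
#' @export
timepoint_similarity <- function(counts, samples, compare_col = "timepoint",
                                 level_a = "diagnosis", level_b = "relapse") {
  check_columns(samples, c("sample_id", "patient_id", compare_col))
  stopifnot(all(samples$sample_id %in% colnames(counts)))
  cpm <- cpm_normalize(counts[, samples$sample_id, drop = FALSE])

  avg_profile <- function(ids) {
    rowMeans(as.matrix(cpm[, ids, drop = FALSE]))
  }
  patients <- unique(samples$patient_id)
  rows <- lapply(patients, function(p) {
    ids_a <- samples$sample_id[samples$patient_id == p &
                                 samples[[compare_col]] == level_a]
    ids_b <- samples$sample_id[samples$patient_id == p &
                                 samples[[compare_col]] == level_b]
    if (length(ids_a) == 0 || length(ids_b) == 0) {
      abort(sprintf("patient %s lacks samples in state %s", p,
                    if (length(ids_a) == 0) level_a else level_b),
            class = "epiclone_validation_error")
    }
    r <- safe_cor(avg_profile(ids_a), avg_profile(ids_b),
                  context = sprintf("similarity for patient %s", p))
    tibble(patient_id = p, r = r)
  })
  dplyr::bind_rows(rows)
}

#' Fraction of one differential peak set found in another
#'
#' `|A intersect B| / |A|`; asymmetric by construction (used to compare
#' differentially accessible peaks in LSC vs non-LSC compartments).
#'
#' @param a,b Character vectors of feature identifiers.
#' @return A single fraction in `[0, 1]`.
#' @export
differential_overlap_fraction <- function(a, b) {
  if (length(a) == 0) {
    abort("overlap fraction undefined for an empty reference set",
          class = "epiclone_validation_error")
  }
  length(intersect(a, b)) / length(unique(a))
}

#' Motif enrichment in differential peaks
#'
#' Hypergeometric tail tests of motif-positive peaks in a foreground set
#' against a background peak universe, in both enrichment and depletion
#' directions, with BH adjustment per direction. Motif scanning itself is
#' not performed; a peak x motif logical annotation is the input.
#'
#' @param foreground Character vector of foreground peak names.
#' @param annotation Logical matrix, peaks (rownames) x motifs (colnames);
#'   the rownames define the background universe.
#' @return Tibble per motif: foreground/background tallies, `odds_ratio`
#'   (`Inf` sentinel when the motif saturates the foreground),
#'   `p_enriched`, `p_depleted`, `padj_enriched`, `padj_depleted`.
#' @export
motif_enrichment <- function(foreground, annotation) {
  stopifnot(is.matrix(annotation) || inherits(annotation, "Matrix"))
  universe <- rownames(annotation)
  missing <- setdiff(foreground, universe)
  if (length(missing) > 0) {
    abort("foreground peaks absent from annotation universe",
          class = "epiclone_validation_error")
  }
  fg <- universe %in% foreground
  n <- sum(fg); N <- length(universe)
  rows <- lapply(colnames(annotation), function(motif) {
    pos <- as.logical(annotation[, motif])
    K <- sum(pos)
    if (K == 0) {
      inform(sprintf("motif %s absent from background; skipped", motif))
      return(NULL)
    }
    k <- sum(fg & pos)
    or <- (k * (N - K - n + k)) / ((n - k) * (K - k))
    tibble(
      motif = motif, n_foreground = n, n_foreground_motif = k,
      n_background = N, n_background_motif = K,
      odds_ratio = ifelse(is.nan(or), Inf, or),
      p_enriched = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      p_depleted = phyper(k, K, N - K, n, lower.tail = TRUE)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$padj_enriched <- p.adjust(out$p_enriched, "BH")
  out$padj_depleted <- p.adjust(out$p_depleted, "BH")
  out
}
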