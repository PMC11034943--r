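# Pre-ranked gene set enrichment: weighted Kolmogorov-Smirnov running-sum
# statistic (weight exponent 1) with a gene-label permutation null and
# signed-ES normalization. The running sum is authored here because the
# enrichment statistic, its permutation scheme and its normalization are
# pinned contracts of this pipeline; fgsea serves as an independent
# cross-check in the test suite.

# Signed enrichment score from sorted hit positions.
# absw: |stat| over the full ranking (decreasing order); pos: sorted hit
# positions. Evaluates the running sum just before and at each hit, the
# only candidate extrema.
running_sum_es <- function(absw, pos, n_total) {
  k <- length(pos)
  if (k == 0) return(NA_real_)
  if (k == n_total) return(0)  # no complement: the set cannot discriminate
  w <- absw[pos]
  if (sum(w) == 0) w <- rep(1, k)  # degenerate: equal hit increments
  W <- sum(w)
  miss <- 1 / (n_total - k)
  cw <- cumsum(w)
  at_hit <- cw / W - (pos - seq_len(k)) * miss
  before_hit <- (cw - w) / W - (pos - seq_len(k)) * miss
  es_max <- max(at_hit)
  es_min <- min(before_hit, 0)
  if (es_max >= -es_min) es_max else es_min
}

#' Pre-ranked gene set enrichment analysis
#'
#' Genes are ranked by a statistic (descending; ties broken by gene name
#' for determinism). Each set's enrichment score (ES) is the extremum of a
#' weighted Kolmogorov-Smirnov running sum: member genes increment by
#' `|stat|` (normalized), non-members decrement by `1/(N - N_h)`. The null
#' is built per set by `n_permutations` random gene-label draws of the
#' same size; p-values and the normalized ES (NES = ES divided by the mean
#' same-sign null magnitude) follow the signed convention, with BH
#' adjustment across sets.
#'
#' @param ranking Tibble with `gene` and `stat` columns (or a named
#'   numeric vector).
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param n_permutations Gene-label permutations per set (default 1000).
#' @param seed Integer seed for the permutation stream (required).
#' @param min_size Sets with fewer ranked members are skipped (default 5).
#' @return Object of class `epiclone_gsea`: tibble with `set`, `size`,
#'   `es`, `nes`, `p`, `padj`, plus attributes `ranking` and `alpha`.
#'   The reporting threshold used downstream is `padj < 0.05`.
#' @export
gsea_preranked <- function(ranking, gene_sets, n_permutations = 1000,
                           seed, min_size = 5) {
  if (missing(seed)) abort("`seed` is required", class = "epiclone_config_error")
  if (is.numeric(ranking) && !is.null(names(ranking))) {
    ranking <- tibble(gene = names(ranking), stat = unname(ranking))
  }
  check_columns(ranking, c("gene", "stat"))
  if (anyDuplicated(ranking$gene)) {
    abort("duplicate genes in ranking", class = "epiclone_validation_error")
  }
  ord <- order(-ranking$stat, ranking$gene)
  genes <- ranking$gene[ord]
  absw <- abs(ranking$stat[ord])
  N <- length(genes)
  set.seed(offset_seed(seed, 606))

  rows <- lapply(names(gene_sets), function(nm) {
    members <- which(genes %in% gene_sets[[nm]])
    k <- length(members)
    if (k == 0) {
      inform(sprintf("set %s has no genes in the ranking; skipped", nm))
      return(NULL)
    }
    if (k < min_size) return(NULL)
    es <- running_sum_es(absw, members, N)
    if (k == N) {
      return(tibble(set = nm, size = k, es = 0, nes = 0, p = 1))
    }
    null_es <- vapply(seq_len(n_permutations), function(b) {
      running_sum_es(absw, sort(sample.int(N, k)), N)
    }, numeric(1))
    if (es >= 0) {
      same <- null_es[null_es >= 0]
      p <- (sum(same >= es) + 1) / (length(same) + 1)
      nes <- if (length(same) > 0 && mean(same) > 0) es / mean(same) else NA_real_
    } else {
      same <- null_es[null_es < 0]
      p <- (sum(same <= es) + 1) / (length(same) + 1)
      nes <- if (length(same) > 0) es / abs(mean(same)) else NA_real_
    }
    tibble(set = nm, size = k, es = es, nes = nes, p = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out$padj <- p.adjust(out$p, "BH")
  structure(out, class = c("epiclone_gsea", class(out)),
            ranking = tibble(gene = genes, stat = ranking$stat[ord]),
            alpha = 0.05)
}
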