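# Decay-weighted gene accessibility scores from a 5-kb tile matrix, the
# relapse signature, and per-cell relapse scoring support.

#' Distance-decay tile weights for a gene
#'
#' Tiles overlapping the gene span `[TSS - 5000, TTS]` get the body weight
#' `1 + e^-1`; flanking tiles at distance `d` (bp between the nearest
#' edges of tile and span) get `exp(-d / 5000) + e^-1`; tiles more than
#' 20,000 bp away, or overlapping another gene's span, get 0. The weight
#' is continuous at the body/flank boundary (both give `1 + e^-1` at
#' `d = 0`).
#'
#' @param gene One-row tibble: `gene`, `chrom`, `start`, `end`, `strand`
#'   (`+`/`-`; the strand decides which end is the TSS).
#' @param tiles Tile tibble for the gene's chromosome: `start`, `end`
#'   (0-based half-open, typically 5,000 bp wide).
#' @param neighbors Optional tibble of other genes (same columns as
#'   `gene`) whose spans zero out colliding tiles.
#' @param max_distance Flank cutoff in bp (default 20,000).
#' @param decay Decay length scale in bp (default 5,000).
#' @return Numeric weight per tile row.
#' @export
gene_tile_weights <- function(gene, tiles, neighbors = NULL,
                              max_distance = 20000, decay = 5000) {
  check_columns(gene, c("chrom", "start", "end", "strand"))
  check_columns(tiles, c("start", "end"))
  span <- gene_span(gene)
  d <- interval_gap(tiles$start, tiles$end, span[1], span[2])
  w <- ifelse(d == 0, 1 + exp(-1),
              ifelse(d > max_distance, 0, exp(-d / decay) + exp(-1)))
  if (!is.null(neighbors) && nrow(neighbors) > 0) {
    for (i in seq_len(nrow(neighbors))) {
      nspan <- gene_span(neighbors[i, ])
      collide <- intervals_overlap(tiles$start, tiles$end, nspan[1], nspan[2])
      w[collide] <- 0
    }
  }
  w
}

# [TSS - 5kb, TTS] in genomic coordinates, honoring strand.
gene_span <- function(gene) {
  if (gene$strand == "+") {
    c(max(gene$start - 5000, 0), gene$end)
  } else {
    c(gene$start, gene$end + 5000)
  }
}

# gap in bp between half-open [s1, e1) and [s2, e2); 0 when they overlap
# or abut
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s2 - e1, s1 - e2))
}

#' Gene accessibility scores from a tile matrix
#'
#' Per sample (or cell), tile insertion counts are depth-normalized
#' (`counts * 1e4 / total insertions`), multiplied by the gene's tile
#' weights, and summed over the tiles in range.
#'
#' @param tile_counts Tiles x samples matrix (dense or sparse), rows
#'   aligned with `tiles`.
#' @param tiles Tile tibble: `chrom`, `start`, `end`.
#' @param genes Gene model tibble: `gene`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param normalize Depth-normalize tile counts first (default `TRUE`).
#' @return Dense matrix, genes x samples. A gene with no in-range tiles
#'   scores 0 (reported once via a message).
#' @export
compute_gene_scores <- function(tile_counts, tiles, genes, normalize = TRUE) {
  check_columns(tiles, c("chrom", "start", "end"))
  check_columns(genes, c("gene", "chrom", "start", "end", "strand"))
  stopifnot(nrow(tile_counts) == nrow(tiles))

  norm <- if (normalize) {
    depth <- Matrix::colSums(tile_counts)
    depth[depth == 0] <- 1
    as.matrix(tile_counts) %*% diag(1e4 / depth, length(depth))
  } else {
    as.matrix(tile_counts)
  }
  colnames(norm) <- colnames(tile_counts)

  scores <- matrix(0, nrow(genes), ncol(norm),
                   dimnames = list(genes$gene, colnames(norm)))
  spans <- t(vapply(seq_len(nrow(genes)),
                    function(i) gene_span(genes[i, ]), numeric(2)))
  empty <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    # only tiles within the flank cutoff of the span can carry weight
    lo <- spans[i, 1] - 20000; hi <- spans[i, 2] + 20000
    near <- which(tiles$chrom == g$chrom & tiles$end > lo & tiles$start < hi)
    if (length(near) == 0) { empty <- c(empty, g$gene); next }
    nb <- which(genes$chrom == g$chrom & seq_len(nrow(genes)) != i &
                  spans[, 2] > lo & spans[, 1] < hi)
    w <- gene_tile_weights(g, tiles[near, ], neighbors = genes[nb, ])
    nz <- which(w > 0)
    if (length(nz) == 0) { empty <- c(empty, g$gene); next }
    scores[i, ] <- w[nz] %*% norm[near[nz], , drop = FALSE]
  }
  if (length(empty) > 0) {
    inform(sprintf("%d gene(s) with no in-range tiles scored 0",
                   length(empty)))
  }
  scores
}

#' Derive the relapse signature from differential gene scores
#'
#' Genes are ranked by the relapse-vs-diagnosis statistic; the top and
#' bottom `n` form the signature. With fewer than `2n` genes the split
#' shrinks evenly (never overlapping), with a message.
#'
#' @param differential Tibble with `feature` (gene) and a ranking
#'   statistic column.
#' @param n Target signature half-size (default 500).
#' @param stat Name of the ranking column (default `log2fc`).
#' @return Object of class `epiclone_signature`: list with `top`,
#'   `bottom` (ordered character vectors, disjoint) and `ranking` tibble.
#' @export
derive_relapse_signature <- function(differential, n = 500, stat = "log2fc") {
  check_columns(differential, c("feature", stat))
  d <- differential[!is.na(differential[[stat]]), ]
  if (nrow(d) < 2) {
    abort("need at least two ranked genes", class = "epiclone_validation_error")
  }
  d <- d[order(-d[[stat]], d$feature), ]
  half <- min(n, floor(nrow(d) / 2))
  if (half < n) {
    inform(sprintf("only %d genes ranked; signature split %d/%d",
                   nrow(d), half, half))
  }
  structure(
    list(top = d$feature[seq_len(half)],
         bottom = rev(d$feature[seq(nrow(d) - half + 1, nrow(d))]),
         ranking = as_tibble(d[c("feature", stat)])),
    class = "epiclone_signature"
  )
}

#' @export
print.epiclone_signature <- function(x, ...) {
  cat(sprintf("Relapse signature: %d up / %d down genes\n",
              length(x$top), length(x$bottom)))
  cat("  top:", paste(utils::head(x$top, 5), collapse = ", "), "...\n")
  invisible(x)
}

#' Score cells (or samples) with a relapse signature
#'
#' Per column of the gene-score matrix: sum of accessibility scores over
#' the signature's top genes minus the sum over its bottom genes.
#' Signature genes missing from the matrix contribute 0 (reported once).
#'
#' @param gene_scores Genes x cells matrix.
#' @param signature An `epiclone_signature`.
#' @return Tibble with `cell` and `relapse_score`.
#' @export
relapse_score_cells <- function(gene_scores, signature) {
  stopifnot(inherits(signature, "epiclone_signature"))
  if (length(signature$top) == 0 && length(signature$bottom) == 0) {
    abort("empty signature", class = "epiclone_validation_error")
  }
  present_top <- intersect(signature$top, rownames(gene_scores))
  present_bot <- intersect(signature$bottom, rownames(gene_scores))
  n_missing <- length(signature$top) + length(signature$bottom) -
    length(present_top) - length(present_bot)
  if (n_missing > 0) {
    inform(sprintf("%d signature gene(s) absent from matrix contribute 0",
                   n_missing))
  }
  top_sum <- if (length(present_top) > 0) {
    Matrix::colSums(gene_scores[present_top, , drop = FALSE])
  } else rep(0, ncol(gene_scores))
  bot_sum <- if (length(present_bot) > 0) {
    Matrix::colSums(gene_scores[present_bot, , drop = FALSE])
  } else rep(0, ncol(gene_scores))
  tibble(cell = colnames(gene_scores),
         relapse_score = unname(top_sum - bot_sum))
}
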