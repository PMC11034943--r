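# Per-sample scATAC QC, SNN clustering, contaminant-cluster removal,
# cluster pseudobulk similarity across timepoints, and per-cell relapse
# scoring (relapse_score_cells lives with the gene-score code).

#' Filter cells on fragment count, FRiP and doublet flag
#'
#' @param qc Tibble with `cell`, `n_fragments`, `frip` and `doublet_flag`
#'   (doublet scoring is upstream; only the flag is consumed here).
#' @param min_fragments,min_frip Retention thresholds.
#' @return The retained rows of `qc`.
#' @export
qc_filter_cells <- function(qc, min_fragments = 1000, min_frip = 0.3) {
  check_columns(qc, c("cell", "n_fragments", "frip", "doublet_flag"))
  dplyr::filter(qc, .data$n_fragments >= min_fragments,
                .data$frip >= min_frip, !.data$doublet_flag)
}

# Shared-nearest-neighbour graph + modularity communities. Rows of `x`
# are the objects to cluster (cells); Jaccard edge weights over the k-NN
# sets; Louvain at the given resolution.
snn_cluster <- function(x, k = 20, resolution = 1, seed = 1L,
                        prune = 1 / 15) {
  n <- nrow(x)
  if (n <= k) {
    abort(sprintf("need more than k = %d cells, got %d", k, n),
          class = "epiclone_validation_error")
  }
  nn <- FNN::get.knn(as.matrix(x), k = k)$nn.index
  # neighbour sets include the cell itself so identical cells share k+1
  sets <- cbind(seq_len(n), nn)
  member <- Matrix::sparseMatrix(
    i = rep(seq_len(n), ncol(sets)), j = as.vector(sets), x = 1,
    dims = c(n, n))
  shared <- Matrix::tcrossprod(member)
  jac <- as(shared, "TsparseMatrix")
  kk <- ncol(sets)
  vals <- jac@x / (2 * kk - jac@x)  # |A n B| / |A u B|
  keep <- vals >= prune & jac@i < jac@j
  g <- igraph::graph_from_data_frame(
    data.frame(from = jac@i[keep] + 1L, to = jac@j[keep] + 1L,
               weight = vals[keep]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  set.seed(offset_seed(seed, 808))
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  cl <- igraph::membership(comm)
  as.integer(cl[as.character(seq_len(n))])
}

#' Cluster cells from an embedding
#'
#' Shared-nearest-neighbour graph (Jaccard weights over `k` neighbours)
#' with Louvain modularity optimization at the given resolution;
#' deterministic for a fixed seed.
#'
#' @param embedding Cells x components matrix (e.g. LSI coordinates).
#' @param cell_meta Optional tibble with `cell` (+ `sample_id`,
#'   `timepoint`) joined onto the result.
#' @param k Neighbours for the SNN graph (default 20).
#' @param resolution Louvain resolution; values toward 0 merge everything
#'   into one cluster.
#' @param seed Integer seed.
#' @return Tibble with `cell`, `cluster` (integer), plus any metadata
#'   columns.
#' @export
cluster_cells <- function(embedding, cell_meta = NULL, k = 20,
                          resolution = 1, seed = 1L) {
  cl <- snn_cluster(embedding, k = k, resolution = resolution, seed = seed)
  out <- tibble(
    cell = rownames(embedding) %||% sprintf("cell_%d", seq_len(nrow(embedding))),
    cluster = cl
  )
  if (!is.null(cell_meta)) out <- dplyr::left_join(out, cell_meta, by = "cell")
  out
}

#' Remove residual healthy-immune contaminant clusters
#'
#' A cluster is removed only when both criteria hold: (a) its mean
#' marker-panel gene accessibility exceeds the other cells' by more than
#' `z_threshold` pooled standard deviations, and (b) it is epigenetically
#' dissimilar to the bulk of the sample — its mean pseudobulk correlation
#' to the other clusters falls below the `similarity_quantile` quantile of
#' all inter-cluster correlations. As a safety rail the filter refuses to
#' drop more than half the cells unless `force = TRUE`.
#'
#' @param clusters Tibble from [cluster_cells()].
#' @param gene_scores Genes x cells matrix.
#' @param markers Character vector of marker genes; defaults to the T/B/
#'   monocyte panel (CD89, TLR4, GZMA, CD247, TCL1, CD37, CD209). Markers
#'   absent from the matrix are skipped with a message.
#' @param z_threshold Marker criterion (default 2).
#' @param similarity_quantile Dissimilarity criterion (default 0.05).
#' @param force Allow removing more than 50% of cells.
#' @return List with `cells` (retained cluster tibble), `removed_clusters`
#'   and the per-cluster `diagnostics` tibble.
#' @export
filter_contaminant_clusters <- function(clusters, gene_scores,
                                        markers = c("CD89", "TLR4", "GZMA",
                                                    "CD247", "TCL1", "CD37",
                                                    "CD209"),
                                        z_threshold = 2,
                                        similarity_quantile = 0.05,
                                        force = FALSE) {
  check_columns(clusters, c("cell", "cluster"))
  present <- intersect(markers, rownames(gene_scores))
  if (length(present) < length(markers)) {
    inform(sprintf("%d marker gene(s) absent from matrix; skipped",
                   length(markers) - length(present)))
  }
  if (length(present) == 0) {
    abort("no marker genes available", class = "epiclone_validation_error")
  }
  gs <- gene_scores[, clusters$cell, drop = FALSE]
  marker_score <- Matrix::colMeans(gs[present, , drop = FALSE])

  ids <- sort(unique(clusters$cluster))
  if (length(ids) < 2) {
    return(list(cells = clusters, removed_clusters = integer(0),
                diagnostics = tibble()))
  }
  pb <- sapply(ids, function(cl) {
    Matrix::rowMeans(gs[, clusters$cluster == cl, drop = FALSE])
  })
  sim <- stats::cor(as.matrix(pb))
  off <- sim[upper.tri(sim)]
  sim_cut <- stats::quantile(off, similarity_quantile)
  mean_sim <- (rowSums(sim) - 1) / (length(ids) - 1)

  diagnostics <- dplyr::bind_rows(lapply(seq_along(ids), function(j) {
    inside <- clusters$cluster == ids[j]
    z <- (mean(marker_score[inside]) - mean(marker_score[!inside])) /
      (sd(marker_score) + 1e-12)
    tibble(cluster = ids[j], marker_z = z, mean_similarity = mean_sim[j],
           n_cells = sum(inside))
  }))
  diagnostics$contaminant <- diagnostics$marker_z > z_threshold &
    diagnostics$mean_similarity < sim_cut

  removed <- diagnostics$cluster[diagnostics$contaminant]
  n_removed <- sum(clusters$cluster %in% removed)
  if (!force && n_removed > nrow(clusters) / 2) {
    warn("contaminant filter would remove >50% of cells; refusing without `force = TRUE`")
    removed <- integer(0)
  }
  list(cells = dplyr::filter(clusters, !.data$cluster %in% removed),
       removed_clusters = removed, diagnostics = diagnostics)
}

#' Cluster-to-cluster pseudobulk chromatin similarity
#'
#' Per-cluster pseudobulk = summed peak counts, CPM-normalized; pairwise
#' Pearson correlation across peaks, with a hierarchical grouping of the
#' clusters. Diagnosis and relapse clusters are compared jointly so that
#' diagnosis clusters grouping with relapse clusters stand out.
#'
#' @param clusters Tibble with `cell`, `cluster` and optionally
#'   `timepoint` (joined into the cluster labels when present).
#' @param counts Peaks x cells matrix.
#' @return Object of class `epiclone_cluster_sim`: `similarity` matrix,
#'   `hclust` grouping, and tidy `pairs` tibble.
#' @export
cluster_pseudobulk_similarity <- function(clusters, counts) {
  check_columns(clusters, c("cell", "cluster"))
  label <- if ("timepoint" %in% names(clusters)) {
    paste(substr(clusters$timepoint, 1, 3), clusters$cluster, sep = "_")
  } else {
    as.character(clusters$cluster)
  }
  ids <- sort(unique(label))
  if (length(ids) < 2) {
    abort("need at least two clusters", class = "epiclone_validation_error")
  }
  pb <- sapply(ids, function(l) {
    Matrix::rowSums(counts[, clusters$cell[label == l], drop = FALSE])
  })
  if (any(colSums(pb) == 0)) {
    abort("zero-count cluster pseudobulk", class = "epiclone_validation_error")
  }
  pb <- as.matrix(cpm_normalize(pb))
  sim <- stats::cor(pb)
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  pairs <- as_tibble(as.table(sim), .name_repair = ~ c("a", "b", "r")) |>
    dplyr::filter(.data$a != .data$b)
  structure(list(similarity = sim, hclust = hc, pairs = pairs),
            class = "epiclone_cluster_sim")
}

#' @export
print.epiclone_cluster_sim <- function(x, ...) {
  cat(sprintf("Cluster pseudobulk similarity: %d clusters\n",
              nrow(x$similarity)))
  print(round(x$similarity, 3))
  invisible(x)
}
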