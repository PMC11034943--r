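# Latent semantic indexing of a healthy single-cell reference, projection
# of query cells into the fitted space, pseudo-single-cell generation from
# bulk cut-site pools, and kNN closest-normal calls.

#' Fit an LSI model on a reference cell-by-peak matrix
#'
#' Counts are binarized; term frequency is the depth-normalized binary
#' profile scaled by a constant; inverse document frequency is
#' `log(1 + N_cells / n_cells_with_feature)`; a truncated SVD of the
#' TF-IDF matrix yields the components. Component 1 is dropped when its
#' correlation with log depth exceeds `depth_cor_limit` in magnitude (it
#' then encodes library size, not biology).
#'
#' @param counts Peaks x cells matrix (sparse or dense).
#' @param n_components Components retained after any depth drop
#'   (default 25, floored at the matrix rank).
#' @param scale_to TF scaling constant (default 1e4).
#' @param binarize Binarize counts first (default `TRUE`).
#' @param depth_cor_limit Threshold for dropping component 1
#'   (default 0.75).
#' @return Object of class `epiclone_lsi`: feature names, `idf`, right
#'   singular vectors `v` (features x components), singular values,
#'   `scale_to`, `binarize`, dropped-component flag, and the reference
#'   `embedding` (cells x components tibble-convertible matrix).
#' @export
fit_lsi <- function(counts, n_components = 25, scale_to = 1e4,
                    binarize = TRUE, depth_cor_limit = 0.75) {
  if (ncol(counts) < n_components + 1) {
    abort("need more cells than components", class = "epiclone_validation_error")
  }
  depth <- Matrix::colSums(counts)
  if (any(depth == 0)) {
    abort("reference contains zero-depth cells", class = "epiclone_validation_error")
  }
  x <- methods::as(counts, "CsparseMatrix")
  if (binarize) x@x <- rep(1, length(x@x))
  observed <- Matrix::rowSums(x) > 0
  if (!all(observed)) {
    inform(sprintf("%d never-observed feature(s) dropped from the model",
                   sum(!observed)))
    x <- x[observed, , drop = FALSE]
  }
  tfidf <- lsi_tfidf(x, scale_to = scale_to)

  # irlba initializes randomly; scope a fixed seed so refits are identical
  # without disturbing the caller's RNG stream
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(90210)

  n_ask <- min(n_components + 1, min(dim(x)) - 1)
  sv <- irlba::irlba(Matrix::t(tfidf$mat), nv = n_ask, nu = n_ask)
  embedding <- sv$u %*% diag(sv$d, n_ask)

  drop1 <- abs(cor(embedding[, 1], log(Matrix::colSums(counts)))) >
    depth_cor_limit
  keep <- if (drop1) 2:n_ask else seq_len(min(n_components, n_ask))
  keep <- keep[seq_len(min(length(keep), n_components))]

  emb <- embedding[, keep, drop = FALSE]
  rownames(emb) <- colnames(counts)
  colnames(emb) <- sprintf("LSI%d", seq_along(keep))
  structure(
    list(features = rownames(x), idf = tfidf$idf,
         v = sv$v[, keep, drop = FALSE], d = sv$d[keep],
         scale_to = scale_to, binarize = binarize,
         dropped_component1 = drop1, embedding = emb),
    class = "epiclone_lsi"
  )
}

# binarized/raw matrix -> TF-IDF; returns matrix and the idf weights used
lsi_tfidf <- function(x, scale_to, idf = NULL) {
  depth <- Matrix::colSums(x)
  depth[depth == 0] <- 1
  tf <- x %*% Matrix::Diagonal(x = scale_to / depth)
  if (is.null(idf)) {
    ff <- Matrix::rowSums(x > 0)
    ff[ff == 0] <- 1
    idf <- log(1 + ncol(x) / ff)
  }
  list(mat = Matrix::Diagonal(x = idf) %*% tf, idf = idf)
}

#' @export
print.epiclone_lsi <- function(x, ...) {
  cat(sprintf("LSI model: %d features, %d components%s\n",
              length(x$features), ncol(x$v),
              if (x$dropped_component1) " (component 1 dropped: depth)" else ""))
  invisible(x)
}

#' Project query cells into a fitted LSI space
#'
#' Query profiles are binarized and TF-normalized exactly as in training,
#' weighted by the *reference* IDF (no refitting), and multiplied onto the
#' stored right singular vectors. Query features are matched to the model
#' feature set by name; missing features are zero-filled. Zero-depth query
#' cells are excluded with a message.
#'
#' @param model An `epiclone_lsi` fit.
#' @param counts Peaks x cells query matrix with rownames.
#' @return Cells x components matrix (rownames = retained cell names).
#' @export
project_cells <- function(model, counts) {
  stopifnot(inherits(model, "epiclone_lsi"))
  if (is.null(rownames(counts))) {
    abort("query counts need feature rownames", class = "epiclone_validation_error")
  }
  x <- methods::as(counts, "CsparseMatrix")
  common <- intersect(model$features, rownames(x))
  mapped <- Matrix::sparseMatrix(
    i = match(common, model$features)[rep(1, 0)], j = integer(0), x = numeric(0),
    dims = c(length(model$features), ncol(x)),
    dimnames = list(model$features, colnames(x)))
  mapped[match(common, model$features), ] <- x[common, , drop = FALSE]
  mapped <- Matrix::drop0(mapped)
  if (model$binarize && length(mapped@x) > 0) mapped@x <- rep(1, length(mapped@x))

  depth <- Matrix::colSums(mapped)
  keep <- depth > 0
  if (!all(keep)) {
    inform(sprintf("%d zero-depth query cell(s) excluded", sum(!keep)))
    mapped <- mapped[, keep, drop = FALSE]
  }
  tfidf <- lsi_tfidf(mapped, scale_to = model$scale_to, idf = model$idf)
  coords <- as.matrix(Matrix::t(tfidf$mat) %*% model$v)
  rownames(coords) <- colnames(mapped)
  colnames(coords) <- sprintf("LSI%d", seq_len(ncol(coords)))
  coords
}

#' Generate pseudo-single cells from a bulk cut-site pool
#'
#' Draws `n_cells` pseudo-cells from a bulk sample's cut sites: within a
#' cell, sites are sampled without replacement; across cells, sampling is
#' with replacement. Sites are then counted against a peak set.
#'
#' @param cutsites Tibble (`chrom`, `pos`) of the bulk sample's cut sites.
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `name`).
#' @param n_cells Number of pseudo-cells (default 250).
#' @param reads_per_cell Cut sites per pseudo-cell (default 10,000).
#' @param seed Integer seed.
#' @return Sparse peaks x pseudo-cells count matrix.
#' @export
make_pseudo_single_cells <- function(cutsites, peaks, n_cells = 250,
                                     reads_per_cell = 10000, seed = 1L) {
  check_columns(cutsites, c("chrom", "pos"))
  if (nrow(cutsites) < reads_per_cell) {
    abort("cut-site pool smaller than reads_per_cell",
          class = "epiclone_validation_error")
  }
  set.seed(offset_seed(seed, 707))
  peak_names <- peaks$name %||% sprintf("peak_%05d", seq_len(nrow(peaks)))
  gr_peaks <- intervals_to_granges(peaks)
  gr_sites <- positions_to_granges(cutsites$chrom, cutsites$pos)
  # peak index per site (NA outside peaks); consensus peaks are disjoint
  hit <- GenomicRanges::findOverlaps(gr_sites, gr_peaks, select = "first")

  cols <- lapply(seq_len(n_cells), function(i) {
    take <- sample.int(nrow(cutsites), reads_per_cell, replace = FALSE)
    idx <- hit[take]
    idx <- idx[!is.na(idx)]
    tab <- tabulate(idx, nrow(peaks))
    nz <- which(tab > 0)
    Matrix::sparseMatrix(i = nz, j = rep(1L, length(nz)), x = tab[nz],
                         dims = c(nrow(peaks), 1L))
  })
  out <- do.call(cbind, cols)
  dimnames(out) <- list(peak_names, sprintf("pseudo_%03d", seq_len(n_cells)))
  out
}

#' Closest-normal cell type by k-nearest neighbours in LSI space
#'
#' Each query cell is labelled by the majority cell type among its `k`
#' nearest reference cells (Euclidean distance in the shared LSI space);
#' label ties are resolved toward the label with the smaller mean
#' distance.
#'
#' @param reference_embedding Cells x components matrix of the reference.
#' @param reference_labels Character vector of cell types, aligned with
#'   the reference rows.
#' @param query_embedding Cells x components matrix from
#'   [project_cells()].
#' @param k Neighbours (default 10).
#' @return Tibble with `cell`, `label`, `vote_fraction`.
#' @export
knn_closest_normal <- function(reference_embedding, reference_labels,
                               query_embedding, k = 10) {
  stopifnot(length(reference_labels) == nrow(reference_embedding))
  if (k > nrow(reference_embedding)) {
    abort("k exceeds reference size", class = "epiclone_validation_error")
  }
  nn <- FNN::get.knnx(reference_embedding, query_embedding, k = k)
  calls <- lapply(seq_len(nrow(query_embedding)), function(i) {
    labs <- reference_labels[nn$nn.index[i, ]]
    d <- nn$nn.dist[i, ]
    votes <- table(labs)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      mean_d <- vapply(top, function(l) mean(d[labs == l]), numeric(1))
      top <- top[which.min(mean_d)]
    }
    tibble(label = top, vote_fraction = max(votes) / k)
  })
  dplyr::bind_cols(
    tibble(cell = rownames(query_embedding) %||%
             sprintf("query_%d", seq_len(nrow(query_embedding)))),
    dplyr::bind_rows(calls)
  )
}

#' Per-sample closest-normal label distribution
#'
#' Aggregates [knn_closest_normal()] calls to the fraction of cells per
#' label within each sample, for diagnosis-vs-relapse differentiation
#' comparisons.
#'
#' @param calls Output of [knn_closest_normal()].
#' @param cell_meta Tibble with `cell` and grouping columns (e.g.
#'   `sample_id`, `timepoint`).
#' @param ... Grouping columns (tidy-select), default `sample_id`.
#' @return Tibble of label fractions per group.
#' @export
summarize_closest_normal <- function(calls, cell_meta, ...) {
  groups <- rlang::enquos(...)
  if (length(groups) == 0) groups <- rlang::quos(.data$sample_id)
  dplyr::inner_join(calls, cell_meta, by = "cell") |>
    dplyr::group_by(!!!groups, .data$label) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop_last") |>
    dplyr::mutate(fraction = n / sum(n)) |>
    dplyr::ungroup()
}
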