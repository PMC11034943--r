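# QC filtering, SNN clustering, contaminant removal, cluster similarity
# and relapse scoring at the single-cell level.

test_that("QC filter drops doublets and is monotone in its thresholds", {
  qc <- tibble::tibble(
    cell = sprintf("c%d", 1:6),
    n_fragments = c(5000, 800, 3000, 2000, 10000, 4000),
    frip = c(0.5, 0.6, 0.2, 0.45, 0.7, 0.5),
    doublet_flag = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  out <- qc_filter_cells(qc, min_fragments = 1000, min_frip = 0.3)
  expect_setequal(out$cell, c("c1", "c4", "c6"))

  all_pass <- qc_filter_cells(dplyr::mutate(qc, doublet_flag = FALSE),
                              min_fragments = 0, min_frip = 0)
  expect_equal(nrow(all_pass), 6)

  counts <- vapply(c(0, 1000, 3000, 6000), function(thr) {
    nrow(qc_filter_cells(qc, min_fragments = thr, min_frip = 0))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("two separated programs cluster perfectly; resolution 0 merges", {
  set.seed(120)
  emb <- rbind(matrix(rnorm(150 * 5, 0), ncol = 5),
               matrix(rnorm(150 * 5, 6), ncol = 5))
  rownames(emb) <- sprintf("c%03d", 1:300)
  truth <- rep(1:2, each = 150)
  cl <- cluster_cells(emb, k = 15, resolution = 0.3, seed = 2)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, truth), 1)

  # on a connected SNN graph, resolution -> 0 merges everything
  one_blob <- matrix(rnorm(120 * 5), ncol = 5,
                     dimnames = list(sprintf("b%03d", 1:120), NULL))
  merged <- cluster_cells(one_blob, k = 15, resolution = 1e-4, seed = 2)
  expect_equal(length(unique(merged$cluster)), 1)

  again <- cluster_cells(emb, k = 15, resolution = 0.3, seed = 2)
  expect_identical(cl, again)
  expect_error(cluster_cells(emb[1:10, ], k = 20),
               class = "epiclone_validation_error")
})

contaminant_fixture <- function(seed = 33) {
  # 3 AML-like clusters sharing a program, plus one marker-high outlier
  set.seed(seed)
  n_genes <- 120
  markers <- c("CD89", "TLR4", "GZMA", "CD247")
  gene_names <- c(markers, sprintf("g%03d", seq_len(n_genes - 4)))
  base <- rnorm(n_genes, 5, 0.3)
  mk <- function(shift, n, marker_boost = 0, own = NULL) {
    prof <- base + rnorm(n_genes, 0, 0.1) * 0
    m <- matrix(rnorm(n_genes * n, 0, 0.4) + prof, n_genes)
    if (!is.null(own)) m[own, ] <- m[own, ] + shift
    m[seq_along(markers), ] <- m[seq_along(markers), ] + marker_boost
    m
  }
  gs <- cbind(mk(2, 60, own = 10:30), mk(2, 60, own = 31:50),
              mk(2, 60, own = 51:70),
              # contaminant: high markers, its own distinct program
              mk(6, 25, marker_boost = 6, own = 80:120))
  rownames(gs) <- gene_names
  colnames(gs) <- sprintf("cell%03d", seq_len(ncol(gs)))
  clusters <- tibble::tibble(
    cell = colnames(gs),
    cluster = rep(1:4, c(60, 60, 60, 25))
  )
  list(gs = gs, clusters = clusters)
}

test_that("contaminant clusters need both high markers and dissimilarity", {
  fx <- contaminant_fixture()
  out <- filter_contaminant_clusters(fx$clusters, fx$gs,
                                     markers = c("CD89", "TLR4", "GZMA",
                                                 "CD247"),
                                     similarity_quantile = 0.2)
  expect_equal(out$removed_clusters, 4)
  expect_false(any(out$cells$cluster == 4))

  # marker-high but similar-to-bulk cluster is retained
  gs2 <- fx$gs
  idx <- fx$clusters$cluster == 4
  gs2[, idx] <- gs2[, sample(which(fx$clusters$cluster == 1), sum(idx),
                             replace = TRUE)]
  gs2[1:4, idx] <- gs2[1:4, idx] + 8
  out2 <- filter_contaminant_clusters(fx$clusters, gs2,
                                      markers = c("CD89", "TLR4", "GZMA",
                                                  "CD247"),
                                      similarity_quantile = 0.2)
  expect_length(out2$removed_clusters, 0)
  expect_equal(nrow(out2$cells), nrow(fx$clusters))
})

test_that("the contaminant filter refuses to remove most of the sample", {
  # an oversized marker-high dissimilar cluster trips the safety rail
  set.seed(81)
  n_genes <- 100
  genes <- c("CD89", "TLR4", sprintf("g%03d", seq_len(n_genes - 2)))
  normal <- matrix(rnorm(n_genes * 40, 5, 0.3), n_genes)
  contam <- matrix(rnorm(n_genes * 120, 5, 0.3), n_genes)
  contam[1:2, ] <- contam[1:2, ] + 8
  contam[40:90, ] <- contam[40:90, ] + 6
  gs <- cbind(normal, contam)
  rownames(gs) <- genes
  colnames(gs) <- sprintf("cell%03d", seq_len(ncol(gs)))
  clusters <- tibble::tibble(cell = colnames(gs),
                             cluster = rep(1:3, c(20, 20, 120)))
  expect_warning(
    out <- filter_contaminant_clusters(clusters, gs,
                                       markers = c("CD89", "TLR4"),
                                       similarity_quantile = 0.6),
    ">50%")
  expect_equal(nrow(out$cells), nrow(clusters))
  # with force = TRUE the same call removes the cluster
  forced <- suppressWarnings(
    filter_contaminant_clusters(clusters, gs, markers = c("CD89", "TLR4"),
                                similarity_quantile = 0.6, force = TRUE))
  expect_equal(forced$removed_clusters, 3)
})

test_that("missing markers are skipped; none available is an error", {
  fx <- contaminant_fixture()
  expect_message(
    filter_contaminant_clusters(fx$clusters, fx$gs,
                                markers = c("CD89", "NOT_A_GENE")),
    "absent")
  expect_error(
    filter_contaminant_clusters(fx$clusters, fx$gs, markers = "NOT_A_GENE"),
    class = "epiclone_validation_error")
})

test_that("cluster similarity is a unit-diagonal symmetric correlation", {
  set.seed(44)
  counts <- matrix(rpois(200 * 90, 10), 200)
  colnames(counts) <- sprintf("c%03d", 1:90)
  clusters <- tibble::tibble(cell = colnames(counts),
                             cluster = rep(1:3, each = 30))
  sim <- cluster_pseudobulk_similarity(clusters, counts)
  m <- sim$similarity
  expect_equal(m, Matrix::t(m), ignore_attr = TRUE)
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_true(all(m >= -1 & m <= 1))

  # a duplicated cluster correlates perfectly off-diagonal
  dup <- clusters
  counts2 <- cbind(counts, counts[, 1:30])
  colnames(counts2) <- c(colnames(counts), sprintf("d%03d", 1:30))
  dup <- dplyr::bind_rows(dup, tibble::tibble(
    cell = sprintf("d%03d", 1:30), cluster = 4))
  sim2 <- cluster_pseudobulk_similarity(dup, counts2)
  expect_equal(sim2$similarity["1", "4"], 1)
})

test_that("a relapse-like diagnosis subpopulation scores with relapse cells", {
  set.seed(55)
  n_genes <- 300
  genes <- sprintf("g%03d", 1:n_genes)
  up <- genes[1:50]; down <- genes[51:100]
  relapse_prof <- rep(1, n_genes); names(relapse_prof) <- genes
  relapse_prof[up] <- 4; relapse_prof[down] <- 0.2
  dx_prof <- rep(1, n_genes); names(dx_prof) <- genes
  dx_prof[down] <- 3

  draw <- function(prof, n) {
    matrix(rpois(n_genes * n, prof * 10), n_genes)
  }
  gs <- cbind(draw(dx_prof, 40),       # ordinary diagnosis cells
              draw(relapse_prof, 15),  # relapse-like diagnosis subpopulation
              draw(relapse_prof, 40))  # relapse cells
  rownames(gs) <- genes
  colnames(gs) <- sprintf("c%03d", seq_len(ncol(gs)))
  sig <- structure(list(top = up, bottom = down),
                   class = "epiclone_signature")
  sc <- relapse_score_cells(gs, sig)
  grp <- rep(c("dx", "dx_relapse_like", "relapse"), c(40, 15, 40))
  means <- tapply(sc$relapse_score, grp, mean)
  expect_gt(means["dx_relapse_like"], means["dx"])
  expect_gt(means["relapse"], means["dx"])
  expect_lt(abs(means["dx_relapse_like"] - means["relapse"]),
            0.2 * abs(means["relapse"] - means["dx"]))
})
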