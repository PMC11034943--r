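# Mito variant QC, heteroplasmy, clone clustering, tree containment,
# frequency dynamics and the convergence machinery.

test_that("heteroplasmy is alt over coverage, missing at zero coverage", {
  alt_fw <- matrix(c(3, 0), 1, 2, dimnames = list("v1", c("a", "b")))
  alt_rev <- matrix(c(2, 0), 1, 2, dimnames = list("v1", c("a", "b")))
  ref_fw <- matrix(c(2, 0), 1, 2, dimnames = list("v1", c("a", "b")))
  ref_rev <- matrix(c(3, 0), 1, 2, dimnames = list("v1", c("a", "b")))
  hp <- compute_heteroplasmy(alt_fw, alt_rev, ref_fw, ref_rev)
  expect_equal(hp$heteroplasmy["v1", "a"], 0.5)
  expect_true(is.na(hp$heteroplasmy["v1", "b"]))
})

test_that("variant QC thresholds are strict inequalities", {
  stats <- tibble::tibble(
    variant = c("boundary_cells", "low_strand", "boundary_cov",
                "boundary_strand", "pass", "no_strand"),
    n_cells_detected = c(3, 40, 10, 10, 10, 10),
    strand_correlation = c(0.9, 0.3, 0.9, 0.65, 0.9, NA),
    mean_coverage = c(50, 50, 10, 50, 50, 50)
  )
  out <- filter_mito_variants(stats)
  expect_equal(out$variant, "pass")
})

test_that("planted artifact variants are exactly the ones removed", {
  cfg <- sim_config(seed = 61, n_mito_cells = 250)
  mito <- simulate_mito_scatac(cfg)
  hp <- compute_heteroplasmy(mito$alt_fw, mito$alt_rev, mito$ref_fw,
                             mito$ref_rev)
  pass <- filter_mito_variants(hp$stats)
  removed <- setdiff(hp$stats$variant, pass$variant)
  expect_setequal(removed, mito$variants$variant[mito$variants$artifact])
})

test_that("planted clones are recovered with high ARI, reproducibly", {
  cfg <- sim_config(seed = 62, n_mito_cells = 400)
  mito <- simulate_mito_scatac(cfg)
  hp <- compute_heteroplasmy(mito$alt_fw, mito$alt_rev, mito$ref_fw,
                             mito$ref_rev)
  keep <- filter_mito_variants(hp$stats)$variant
  fit <- cluster_mitoclones(hp$heteroplasmy[keep, ], cell_meta = mito$cells,
                            resolution = 0.5, seed = 6)
  ari <- mclust::adjustedRandIndex(fit$assignments$clone,
                                   mito$cells$true_clone)
  expect_gte(ari, 0.95)
  again <- cluster_mitoclones(hp$heteroplasmy[keep, ],
                              cell_meta = mito$cells,
                              resolution = 0.5, seed = 6)
  expect_identical(fit$assignments, again$assignments)
  expect_false(any(fit$flags$low_het_flag))
})

test_that("an all-zero binarized matrix collapses to one clone", {
  het <- matrix(0.01, 3, 30,
                dimnames = list(sprintf("v%d", 1:3), sprintf("c%d", 1:30)))
  expect_warning(fit <- cluster_mitoclones(het, binarize_threshold = 0.1),
                 "single clone")
  expect_equal(unique(fit$assignments$clone), 1L)
})

test_that("nested variant sets produce the forced chain and siblings", {
  chain <- matrix(
    c(0.8, 0.8, 0.8,
      0.0, 0.8, 0.8,
      0.0, 0.0, 0.8),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("v1", "v2", "v3"), c("cl1", "cl2", "cl3")))
  tree <- infer_clone_tree(chain)
  expect_equal(tree$edges$parent[tree$edges$clone == "cl3"], "cl2")
  expect_equal(tree$edges$parent[tree$edges$clone == "cl2"], "cl1")
  expect_true(is.na(tree$edges$parent[tree$edges$clone == "cl1"]))
  expect_equal(tree$root_variants, "v1")

  siblings <- matrix(
    c(0.8, 0.8, 0.8,
      0.0, 0.8, 0.0,
      0.0, 0.0, 0.8),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("v0", "va", "vb"), c("root", "A", "B")))
  tr2 <- infer_clone_tree(siblings)
  expect_equal(tr2$edges$parent[tr2$edges$clone == "A"], "root")
  expect_equal(tr2$edges$parent[tr2$edges$clone == "B"], "root")
  expect_equal(tr2$root_variants, "v0")
})

test_that("the planted clone tree is recovered isomorphically", {
  cfg <- sim_config(seed = 63, n_mito_cells = 400)
  mito <- simulate_mito_scatac(cfg)
  hp <- compute_heteroplasmy(mito$alt_fw, mito$alt_rev, mito$ref_fw,
                             mito$ref_rev)
  keep <- filter_mito_variants(hp$stats)$variant
  fit <- cluster_mitoclones(hp$heteroplasmy[keep, ], cell_meta = mito$cells,
                            resolution = 0.5, seed = 6)
  tree <- infer_clone_tree(fit$cluster_het)
  expect_equal(nrow(tree$conflicts), 0)

  # map recovered clones to planted clones via their defining variant sets
  planted <- setNames(mito$tree$clone, vapply(mito$tree$variants, function(v)
    paste(sort(v), collapse = "|"), character(1)))
  key <- vapply(tree$edges$clone, function(cl)
    paste(sort(tree$defining[[cl]]), collapse = "|"), character(1))
  expect_true(all(key %in% names(planted)))
  mapped <- setNames(unname(planted[key]), tree$edges$clone)
  # recovered parent relation must match the planted one clone-for-clone
  for (i in seq_len(nrow(tree$edges))) {
    planted_parent <- mito$tree$parent[mito$tree$clone == mapped[i]]
    rec_parent <- tree$edges$parent[i]
    if (is.na(rec_parent)) {
      expect_true(is.na(planted_parent))
    } else {
      expect_equal(unname(mapped[rec_parent]), planted_parent)
    }
  }
})

test_that("clone frequencies conserve counts and flag planted expansions", {
  a <- tibble::tibble(
    cell = sprintf("c%d", 1:60),
    clone = rep(c("x", "y", "z"), 20),
    timepoint = rep(c("diagnosis", "relapse"), each = 30)
  )
  fr <- clone_frequencies(a)
  expect_equal(sum(fr$freq_diagnosis), 1)
  expect_equal(sum(fr$freq_relapse), 1)

  # planted 0.2% -> 36% expansion at 3,000 cells per timepoint
  set.seed(64)
  n <- 3000
  dx <- sample(c("expanding", "other"), n, replace = TRUE,
               prob = c(0.002, 0.998))
  rel <- sample(c("expanding", "other"), n, replace = TRUE,
                prob = c(0.36, 0.64))
  b <- tibble::tibble(
    cell = sprintf("c%d", 1:(2 * n)),
    clone = c(dx, rel),
    timepoint = rep(c("diagnosis", "relapse"), each = n)
  )
  fr2 <- clone_frequencies(b)
  row <- fr2[fr2$clone == "expanding", ]
  expect_true(row$significant)
  expect_equal(row$direction, "expansion")
  expect_error(clone_frequencies(a[a$timepoint == "relapse", ]),
               class = "epiclone_validation_error")
})

test_that("identical clone profiles make the t-test degenerate", {
  counts <- matrix(rpois(100 * 80, 10), 100)
  counts <- cbind(counts[, 1:40], counts[, 1:40])  # mirrored profiles
  colnames(counts) <- sprintf("c%d", 1:80)
  a <- tibble::tibble(
    cell = colnames(counts),
    clone = rep(rep(c("p", "q"), each = 20), 2),
    timepoint = rep(c("diagnosis", "relapse"), each = 40)
  )
  expect_error(convergence_analysis(a, counts),
               class = "epiclone_zero_variance")
})

test_that("convergence mode drives the similarity test, stationary does not", {
  cfg <- sim_config(seed = 65, n_mito_cells = 250)
  on <- simulate_mito_scatac(cfg, convergence = "on")
  off <- simulate_mito_scatac(cfg, convergence = "off")
  run <- function(mito) {
    a <- dplyr::rename(mito$cells, clone = true_clone)
    convergence_analysis(a, mito$peak_counts)
  }
  cv_on <- run(on)
  expect_true(cv_on$convergent)
  expect_gt(cv_on$mean_rel, cv_on$mean_dx)
  cv_off <- run(off)
  expect_gt(cv_off$p, 0.05)
})

test_that("shift concordance sees shared shifts and rejects zero variance", {
  set.seed(66)
  n_peaks <- 400
  base <- exp(rnorm(n_peaks, 3, 0.5))
  shift <- exp(c(rnorm(100, 1, 0.3), rnorm(n_peaks - 100, 0, 0.05)))
  draw <- function(mu, n) matrix(rpois(n_peaks * n, mu), n_peaks)
  counts <- cbind(draw(base, 30), draw(base, 30),
                  draw(base * shift, 30), draw(base * shift, 30))
  colnames(counts) <- sprintf("c%d", seq_len(ncol(counts)))
  a <- tibble::tibble(
    cell = colnames(counts),
    clone = rep(c("m1", "m2", "m1", "m2"), each = 30),
    timepoint = rep(c("diagnosis", "relapse"), each = 60)
  )
  cc <- clone_shift_concordance(a, counts)
  expect_gt(cc$correlation["m1", "m2"], 0.5)

  # independent shifts decorrelate
  shift2 <- exp(rnorm(n_peaks, 0, 0.8))
  counts2 <- cbind(draw(base, 30), draw(base, 30),
                   draw(base * shift, 30), draw(base * shift2, 30))
  colnames(counts2) <- colnames(counts)
  cc2 <- clone_shift_concordance(a, counts2)
  expect_lt(abs(cc2$correlation["m1", "m2"]),
            cc$correlation["m1", "m2"])

  # a clone missing at one timepoint is dropped with a message
  a3 <- a[!(a$clone == "m2" & a$timepoint == "relapse"), ]
  expect_error(expect_message(clone_shift_concordance(a3, counts), "m2"),
               class = "epiclone_validation_error")
})
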