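# Mutation classification, patient binning, gene dynamics and survival.

mk_mut <- function(vaf_dx, vaf_rel, patient = "P1", gene = "TET2",
                   quantifiable = TRUE, present_dx = NA, present_rel = NA,
                   tier = 1) {
  tibble::tibble(
    patient_id = patient, gene = gene,
    variant_id = paste0(patient, "_", seq_along(vaf_dx)),
    vaf_dx = vaf_dx, vaf_rel = vaf_rel, quantifiable = quantifiable,
    present_dx = present_dx, present_rel = present_rel, tier = tier
  )
}

test_that("VAF rule matches the truth table at and around the boundaries", {
  cases <- tibble::tribble(
    ~vaf_dx, ~vaf_rel, ~expected,
    0.02, 0.40, "gained",
    0.049, 0.101, "gained",
    0.30, 0.01, "lost",
    0.101, 0.049, "lost",
    0.04, 0.08, "stable",   # gain upper bound not met
    0.05, 0.40, "stable",   # dx exactly at the lower threshold
    0.02, 0.10, "stable",   # rel exactly at the upper threshold
    0.10, 0.01, "stable",   # dx exactly at the upper threshold
    0.30, 0.05, "stable",   # rel exactly at the lower threshold
    0.20, 0.20, "stable",
    0.00, 0.11, "gained",
    0.00, 0.06, "stable"    # absent at dx, relapse VAF in (0.05, 0.1]
  )
  got <- classify_mutations(mk_mut(cases$vaf_dx, cases$vaf_rel))
  expect_equal(as.character(got$class), cases$expected)
  for (i in seq_len(nrow(cases))) {
    expect_identical(oracle_classify(cases$vaf_dx[i], cases$vaf_rel[i]),
                     cases$expected[i])
  }
})

test_that("non-quantifiable variants classify from presence calls", {
  m <- tibble::tibble(
    patient_id = "P1", gene = c("FLT3", "NPM1", "FLT3"),
    variant_id = c("v1", "v2", "v3"),
    vaf_dx = NA_real_, vaf_rel = NA_real_, quantifiable = FALSE,
    present_dx = c(FALSE, TRUE, TRUE),
    present_rel = c(TRUE, FALSE, TRUE), tier = 1
  )
  expect_equal(as.character(classify_mutations(m)$class),
               c("gained", "lost", "stable"))
})

test_that("missing VAF on a quantifiable variant is a validation error", {
  expect_error(classify_mutations(mk_mut(NA_real_, 0.2)),
               class = "epiclone_validation_error")
})

test_that("four-bin mapping follows the gained/lost tallies", {
  combos <- list(
    list(classes = c("stable", "stable"), bin = "Stable"),
    list(classes = c("gained", "stable"), bin = "Gain"),
    list(classes = c("lost", "stable"), bin = "Loss"),
    list(classes = c("gained", "lost"), bin = "GainAndLoss"),
    list(classes = c("gained", "gained", "lost"), bin = "GainAndLoss")
  )
  for (cc in combos) {
    cl <- tibble::tibble(
      patient_id = "P1", gene = "X",
      class = factor(cc$classes, levels = c("gained", "lost", "stable"))
    )
    got <- bin_patients(cl)
    expect_equal(as.character(got$bin), cc$bin)
    expect_equal(got$clonality, ifelse(cc$bin == "Stable", "stable",
                                       "unstable"))
  }
})

test_that("evaluability filter drops Tier 3 and patients missing a timepoint", {
  m <- dplyr::bind_rows(
    mk_mut(0.2, 0.3, patient = "A"),
    mk_mut(0.2, NA_real_, patient = "B"),          # missing relapse VAF
    mk_mut(0.3, 0.25, patient = "C", tier = 3),    # only a Tier 3 variant
    tibble::tibble(patient_id = "D", gene = "FLT3", variant_id = "D_1",
                   vaf_dx = NA, vaf_rel = NA, quantifiable = FALSE,
                   present_dx = TRUE, present_rel = TRUE, tier = 1)
  )
  out <- filter_evaluable_patients(m)
  expect_setequal(unique(out$patient_id), c("A", "D"))
  expect_false(any(out$tier == 3))
})

test_that("recovered bins equal planted bins on a simulated cohort", {
  cfg <- sim_config(seed = 31, n_patients = 200)
  coh <- simulate_mutation_cohort(cfg)
  bins <- coh$mutations |>
    filter_evaluable_patients() |>
    classify_mutations() |>
    bin_patients()
  expect_equal(nrow(bins), 200)
  truth <- dplyr::rename(coh$truth, true_bin = bin)
  merged <- dplyr::inner_join(bins, truth, by = "patient_id")
  expect_equal(as.character(merged$bin), merged$true_bin)
})

test_that("degenerate probability vector plants an all-stable cohort", {
  cfg <- sim_config(seed = 5, n_patients = 40,
                    bin_probabilities = c(Stable = 1, Gain = 0, Loss = 0,
                                          GainAndLoss = 0))
  coh <- simulate_mutation_cohort(cfg)
  cls <- classify_mutations(coh$mutations)
  expect_true(all(cls$class == "stable"))
  expect_true(all(bin_patients(cls)$bin == "Stable"))
})

test_that("gene dynamics equal an independent tally and respect the event floor", {
  cfg <- sim_config(seed = 13, n_patients = 120)
  coh <- simulate_mutation_cohort(cfg)
  cls <- classify_mutations(coh$mutations)
  summ <- summarize_gene_dynamics(cls, min_events = 20)
  # brute-force tally per gene
  for (g in sample(unique(cls$gene), 5)) {
    sub <- cls[cls$gene == g, ]
    row <- summ[summ$gene == g, ]
    expect_equal(row$n_gained, sum(sub$class == "gained"))
    expect_equal(row$n_lost, sum(sub$class == "lost"))
    expect_equal(row$n_stable, sum(sub$class == "stable"))
    expect_equal(row$n_events, nrow(sub))
    expect_equal(row$in_ternary, nrow(sub) >= 20)
  }
  expect_equal(summ$frac_gained + summ$frac_lost + summ$frac_stable,
               rep(1, nrow(summ)))
})

test_that("single-class gene lands on a ternary vertex", {
  cl <- tibble::tibble(patient_id = sprintf("P%d", 1:10), gene = "WT1",
                       class = factor("gained",
                                      levels = c("gained", "lost", "stable")))
  summ <- summarize_gene_dynamics(cl, min_events = 5)
  expect_equal(c(summ$frac_gained, summ$frac_lost, summ$frac_stable),
               c(1, 0, 0))
})

test_that("exchangeable groups give HR 1 and log-rank p 1", {
  times <- c(100, 200, 300, 400, 150, 250)
  d <- tibble::tibble(
    patient_id = sprintf("P%d", 1:12),
    clonality = rep(c("stable", "unstable"), each = 6)
  )
  clin <- tibble::tibble(
    patient_id = d$patient_id,
    age = 60, sex = rep(c("F", "M"), 6),
    days_to_relapse = rep(times, 2), relapse_event = TRUE
  )
  bins <- dplyr::mutate(d, bin = "Stable")
  out <- compare_survival(bins, clin)
  expect_equal(out$hr, 1, tolerance = 1e-6)
  expect_equal(out$logrank_p, 1, tolerance = 1e-6)
})

test_that("log-rank statistic agrees with a label-permutation reference", {
  set.seed(204)
  n <- 16
  d <- tibble::tibble(
    patient_id = sprintf("P%d", seq_len(n)),
    clonality = rep(c("stable", "unstable"), each = n / 2)
  )
  clin <- tibble::tibble(
    patient_id = d$patient_id, age = 60, sex = "F",
    days_to_relapse = c(rexp(n / 2, 1 / 150), rexp(n / 2, 1 / 400)),
    relapse_event = TRUE
  )
  out <- compare_survival(d, clin)
  # permutation null of the log-rank chi-square
  obs <- out$logrank_chisq
  perm <- replicate(4000, {
    d2 <- d
    d2$clonality <- sample(d2$clonality)
    dd <- dplyr::inner_join(d2, clin, by = "patient_id")
    survival::survdiff(
      survival::Surv(days_to_relapse, relapse_event) ~ clonality,
      data = dd)$chisq
  })
  p_perm <- mean(perm >= obs)
  expect_lt(abs(p_perm - out$logrank_p), 0.035)
})

test_that("planted hazard ratio is recovered across replicates", {
  hits <- 0
  for (s in 1:20) {
    cfg <- sim_config(seed = 700 + s, n_patients = 1000,
                      bin_probabilities = c(Stable = 0.5, Gain = 0.2,
                                            Loss = 0.15, GainAndLoss = 0.15),
                      hr_stable = 1.5, censor_prob = 0)
    coh <- simulate_mutation_cohort(cfg)
    bins <- bin_patients(classify_mutations(coh$mutations))
    fit <- compare_survival(bins, coh$clinical)
    if (fit$hr >= 1.3 && fit$hr <= 1.7) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("panel rules keep major-clone non-Tier-3 variants only", {
  v <- tibble::tibble(
    variant_id = sprintf("v%d", 1:4),
    vaf_dx = c(0.04, 0.2, 0.06, 0.5),
    vaf_rel = c(0.04, 0.3, 0.01, 0.4),
    tier = c(1, 3, 1, NA)
  )
  expect_warning(out <- apply_panel_rules(v), "missing tier")
  expect_equal(out$variant_id, "v3")  # v1 below 5%, v2 Tier 3, v4 no tier
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 99, n_patients = 30)
  a <- simulate_mutation_cohort(cfg)
  b <- simulate_mutation_cohort(cfg)
  expect_identical(a, b)
})

test_that("invalid probability vector raises a configuration error", {
  expect_error(sim_config(bin_probabilities = c(0.5, 0.5, 0.5, -0.5)),
               class = "epiclone_config_error")
  expect_error(sim_config(bin_probabilities = c(0.3, 0.3, 0.3)),
               class = "epiclone_config_error")
})
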