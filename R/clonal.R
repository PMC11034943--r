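# Mutation-dynamics classification between diagnosis and relapse, patient
# clonal binning, gene-level dynamics, and relapse-free survival comparison.

#' Filter a cohort to patients evaluable at both timepoints
#'
#' Tier 3 variants (synonymous / unknown significance) are removed first;
#' a patient is retained only if every remaining variant carries the values
#' its classification needs: both VAFs for quantifiable variants, both
#' presence calls otherwise.
#'
#' @param mutations Mutation tibble with columns `patient_id`, `gene`,
#'   `variant_id`, `vaf_dx`, `vaf_rel`, `quantifiable`, `present_dx`,
#'   `present_rel` and optionally `tier`.
#' @return The filtered mutation tibble (possibly zero rows).
#' @export
filter_evaluable_patients <- function(mutations) {
  check_columns(mutations, c("patient_id", "vaf_dx", "vaf_rel",
                             "quantifiable", "present_dx", "present_rel"))
  if ("tier" %in% names(mutations)) {
    mutations <- dplyr::filter(mutations, is.na(.data$tier) | .data$tier != 3)
  }
  evaluable <- with(mutations, ifelse(
    quantifiable,
    !is.na(vaf_dx) & !is.na(vaf_rel),
    !is.na(present_dx) & !is.na(present_rel)
  ))
  ok_patients <- mutations$patient_id[stats::ave(evaluable, mutations$patient_id,
                                                 FUN = all) > 0]
  dplyr::filter(mutations, .data$patient_id %in% ok_patients)
}

#' Classify mutation dynamics between diagnosis and relapse
#'
#' A quantifiable mutation is *gained* if its VAF moves from below 0.05 at
#' diagnosis to above 0.10 at relapse, *lost* for the reverse, and *stable*
#' otherwise (inequalities strict: a VAF of exactly 0.05 or 0.10 can never
#' trigger gain or loss). Non-quantifiable variants (e.g. FLT3-ITD, NPM1
#' insertions) are classified from their presence calls.
#'
#' @param mutations Mutation tibble (see [filter_evaluable_patients()]).
#' @param vaf_low,vaf_high Rule thresholds; defaults 0.05 and 0.10.
#' @return The input with a `class` factor column
#'   (`gained`/`lost`/`stable`).
#' @export
#' @examples
#' m <- tibble::tibble(patient_id = "P1", gene = "WT1", variant_id = "v1",
#'                     vaf_dx = 0.02, vaf_rel = 0.4, quantifiable = TRUE,
#'                     present_dx = NA, present_rel = NA)
#' classify_mutations(m)$class
classify_mutations <- function(mutations, vaf_low = 0.05, vaf_high = 0.10) {
  check_columns(mutations, c("vaf_dx", "vaf_rel", "quantifiable",
                             "present_dx", "present_rel"))
  q <- mutations$quantifiable
  if (any(q & (is.na(mutations$vaf_dx) | is.na(mutations$vaf_rel)))) {
    abort("quantifiable mutation with missing VAF; filter the cohort first",
          class = "epiclone_validation_error")
  }
  cls <- rep("stable", nrow(mutations))
  gained_q <- q & mutations$vaf_dx < vaf_low & mutations$vaf_rel > vaf_high
  lost_q <- q & mutations$vaf_dx > vaf_high & mutations$vaf_rel < vaf_low
  gained_p <- !q & !mutations$present_dx & mutations$present_rel
  lost_p <- !q & mutations$present_dx & !mutations$present_rel
  cls[gained_q | gained_p] <- "gained"
  cls[lost_q | lost_p] <- "lost"
  dplyr::mutate(mutations,
                class = factor(cls, levels = c("gained", "lost", "stable")))
}

#' Bin patients by clonal evolution pattern
#'
#' `Stable` = no gained and no lost mutations; `Gain` = at least one gained
#' and none lost; `Loss` = the reverse; `GainAndLoss` = both. Clonality is
#' `stable` only for the Stable bin — "unstable" means any change in the
#' mutation complement at relapse.
#'
#' @param classified Output of [classify_mutations()].
#' @return Tibble with `patient_id`, `bin` (ordered factor) and `clonality`
#'   (`stable`/`unstable`).
#' @export
bin_patients <- function(classified) {
  check_columns(classified, c("patient_id", "class"))
  out <- classified |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_gained = sum(.data$class == "gained"),
      n_lost = sum(.data$class == "lost"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bin = dplyr::case_when(
        n_gained == 0 & n_lost == 0 ~ "Stable",
        n_gained > 0 & n_lost == 0 ~ "Gain",
        n_gained == 0 & n_lost > 0 ~ "Loss",
        TRUE ~ "GainAndLoss"
      ),
      bin = factor(bin, levels = c("Stable", "Gain", "Loss", "GainAndLoss")),
      clonality = ifelse(bin == "Stable", "stable", "unstable")
    )
  dplyr::select(out, "patient_id", "bin", "clonality")
}

#' Per-gene mutation dynamics summary
#'
#' Tallies gained / lost / stable events per gene, the percentage of
#' patients carrying a mutation in the gene, and ternary coordinates
#' (event fractions summing to 1). The ternary view is restricted to genes
#' with at least `min_events` events; the full table is unrestricted and
#' flags eligibility in `in_ternary`.
#'
#' @param classified Output of [classify_mutations()].
#' @param min_events Minimum events for the ternary plot (default 20).
#' @return Tibble with per-gene counts, `pct_patients_mutated`,
#'   `pct_patients_gained`, fractions `frac_gained`/`frac_lost`/
#'   `frac_stable`, `n_events` and `in_ternary`.
#' @export
summarize_gene_dynamics <- function(classified, min_events = 20) {
  check_columns(classified, c("patient_id", "gene", "class"))
  n_patients <- dplyr::n_distinct(classified$patient_id)
  classified |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_gained = sum(.data$class == "gained"),
      n_lost = sum(.data$class == "lost"),
      n_stable = sum(.data$class == "stable"),
      n_patients_mutated = dplyr::n_distinct(.data$patient_id),
      n_patients_gained = dplyr::n_distinct(
        .data$patient_id[.data$class == "gained"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_events = n_gained + n_lost + n_stable,
      pct_patients_mutated = 100 * n_patients_mutated / n_patients,
      pct_patients_gained = 100 * n_patients_gained / n_patients,
      frac_gained = n_gained / n_events,
      frac_lost = n_lost / n_events,
      frac_stable = n_stable / n_events,
      in_ternary = n_events >= min_events
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_events))
}

#' Compare relapse-free survival between stable and unstable clonality
#'
#' Kaplan-Meier curves and a log-rank test for stable vs unstable patients,
#' plus a Cox proportional-hazards model (Efron tie handling) adjusted for
#' age and sex. The reported hazard ratio is for stable relative to
#' unstable clonality.
#'
#' @param bins Output of [bin_patients()].
#' @param clinical Clinical tibble with `patient_id`, `age`, `sex`,
#'   `days_to_relapse`, `relapse_event`.
#' @return An object of class `epiclone_survcmp`: list with `km` (survfit),
#'   `logrank_p`, `cox` (coxph fit), `hr`, `hr_ci` (95%), `cox_p`, and the
#'   analysis table `data`. Patients missing age or sex are dropped from
#'   the adjusted model with a warning.
#' @export
compare_survival <- function(bins, clinical) {
  check_columns(bins, c("patient_id", "clonality"))
  check_columns(clinical, c("patient_id", "age", "sex", "days_to_relapse",
                            "relapse_event"))
  d <- dplyr::inner_join(bins, clinical, by = "patient_id") |>
    dplyr::mutate(clonality = factor(.data$clonality,
                                     levels = c("unstable", "stable")))
  if (length(unique(d$clonality)) < 2) {
    abort("both clonality groups required", class = "epiclone_validation_error")
  }
  if (all(!d$relapse_event)) {
    abort("log-rank undefined: no observed events",
          class = "epiclone_validation_error")
  }
  drop <- is.na(d$age) | is.na(d$sex)
  if (any(drop)) {
    warn(sprintf("dropping %d patient(s) with missing age/sex from the Cox model",
                 sum(drop)))
  }
  km <- survival::survfit(
    survival::Surv(days_to_relapse, relapse_event) ~ clonality, data = d)
  lr <- survival::survdiff(
    survival::Surv(days_to_relapse, relapse_event) ~ clonality, data = d)
  logrank_p <- stats::pchisq(lr$chisq, df = length(lr$n) - 1,
                             lower.tail = FALSE)
  covars <- c("age", "sex")[c(dplyr::n_distinct(d$age[!drop]) > 1,
                              dplyr::n_distinct(d$sex[!drop]) > 1)]
  if (length(covars) < 2) {
    inform("constant covariate(s) dropped from the Cox model")
  }
  form <- stats::as.formula(paste(
    "survival::Surv(days_to_relapse, relapse_event) ~",
    paste(c("clonality", covars), collapse = " + ")))
  cox <- survival::coxph(form, data = d[!drop, ], ties = "efron")
  s <- summary(cox)
  row <- grep("^clonality", rownames(s$coefficients))
  structure(
    list(km = km, logrank_p = logrank_p, logrank_chisq = lr$chisq, cox = cox,
         hr = unname(s$coefficients[row, "exp(coef)"]),
         hr_ci = unname(s$conf.int[row, c("lower .95", "upper .95")]),
         cox_p = unname(s$coefficients[row, "Pr(>|z|)"]),
         data = d),
    class = "epiclone_survcmp"
  )
}

#' @export
print.epiclone_survcmp <- function(x, ...) {
  cat("Relapse-free survival, stable vs unstable clonality\n")
  cat(sprintf("  n = %d patients, %d events\n", nrow(x$data),
              sum(x$data$relapse_event)))
  cat(sprintf("  log-rank p = %.4g\n", x$logrank_p))
  cat(sprintf("  Cox HR (stable vs unstable, age/sex adjusted) = %.3f [%.3f, %.3f], p = %.4g\n",
              x$hr, x$hr_ci[1], x$hr_ci[2], x$cox_p))
  invisible(x)
}

#' Apply targeted-panel variant rules
#'
#' Keeps 'major clone' variants: mean VAF above 0.05 at either timepoint.
#' Tier 3 variants are dropped; variants with missing tier are treated as
#' Tier 3 and dropped with a warning.
#'
#' @param variants Tibble with `vaf_dx`, `vaf_rel` and `tier`.
#' @param vaf_cutoff Major-clone threshold (default 0.05, strict).
#' @return Filtered tibble of `MutationRecord`-shaped rows.
#' @export
apply_panel_rules <- function(variants, vaf_cutoff = 0.05) {
  check_columns(variants, c("vaf_dx", "vaf_rel"))
  if (!"tier" %in% names(variants)) variants$tier <- NA_integer_
  n_na <- sum(is.na(variants$tier))
  if (n_na > 0) {
    warn(sprintf("%d variant(s) with missing tier treated as Tier 3 and dropped",
                 n_na))
  }
  variants |>
    dplyr::filter(!is.na(.data$tier), .data$tier != 3) |>
    dplyr::filter(
      pmax(.data$vaf_dx, .data$vaf_rel, na.rm = TRUE) > vaf_cutoff)
}
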