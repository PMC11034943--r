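# broom-style tidiers for the package's fitted objects.

#' Tidy a survival comparison
#'
#' @param x An `epiclone_survcmp` object.
#' @param ... Unused.
#' @return One row per Cox model term: `term`, `estimate` (hazard ratio),
#'   `conf.low`, `conf.high`, `p.value`.
#' @exportS3Method generics::tidy
tidy.epiclone_survcmp <- function(x, ...) {
  s <- summary(x$cox)
  tibble(
    term = rownames(s$coefficients),
    estimate = unname(s$coefficients[, "exp(coef)"]),
    conf.low = unname(s$conf.int[, "lower .95"]),
    conf.high = unname(s$conf.int[, "upper .95"]),
    p.value = unname(s$coefficients[, "Pr(>|z|)"])
  )
}

#' @rdname tidy.epiclone_survcmp
#' @return `glance()`: one row with `n`, `n_events`, `logrank_p`, `hr`,
#'   `cox_p`.
#' @exportS3Method generics::glance
glance.epiclone_survcmp <- function(x, ...) {
  tibble(n = nrow(x$data), n_events = sum(x$data$relapse_event),
         logrank_p = x$logrank_p, hr = x$hr, cox_p = x$cox_p)
}

#' Tidy an LSI model
#'
#' @param x An `epiclone_lsi` object.
#' @param ... Unused.
#' @return The reference embedding as a tibble (`cell`, `LSI1`, ...).
#' @exportS3Method generics::tidy
tidy.epiclone_lsi <- function(x, ...) {
  dplyr::bind_cols(tibble(cell = rownames(x$embedding)),
                   as_tibble(x$embedding))
}

#' @rdname tidy.epiclone_lsi
#' @exportS3Method generics::glance
glance.epiclone_lsi <- function(x, ...) {
  tibble(n_features = length(x$features), n_components = ncol(x$v),
         dropped_component1 = x$dropped_component1)
}

#' Tidy a clone tree
#'
#' @param x An `epiclone_clone_tree` object.
#' @param ... Unused.
#' @return Edge-list tibble: `clone`, `parent`, `n_defining_variants`,
#'   `exclusive_variants`.
#' @exportS3Method generics::tidy
tidy.epiclone_clone_tree <- function(x, ...) {
  x$edges |>
    dplyr::mutate(
      n_defining_variants = lengths(x$defining[.data$clone]),
      exclusive_variants = vapply(.data$clone, function(cl) {
        p <- x$edges$parent[x$edges$clone == cl]
        excl <- if (is.na(p)) x$defining[[cl]] else
          setdiff(x$defining[[cl]], x$defining[[p]])
        paste(excl, collapse = ",")
      }, character(1))
    )
}

#' Tidy a convergence analysis
#'
#' @param x An `epiclone_convergence` object.
#' @param ... Unused.
#' @return The clone-pair similarity tibble (`timepoint`, `r`).
#' @exportS3Method generics::tidy
tidy.epiclone_convergence <- function(x, ...) x$similarity

#' @rdname tidy.epiclone_convergence
#' @exportS3Method generics::glance
glance.epiclone_convergence <- function(x, ...) {
  tibble(mean_dx = x$mean_dx, mean_rel = x$mean_rel, t = x$t, p = x$p,
         convergent = x$convergent)
}

#' Tidy a GSEA result
#'
#' @param x An `epiclone_gsea` object.
#' @param ... Unused.
#' @return The per-set tibble, ordered by adjusted p-value.
#' @exportS3Method generics::tidy
tidy.epiclone_gsea <- function(x, ...) {
  dplyr::arrange(as_tibble(x), .data$padj)
}
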