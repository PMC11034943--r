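# ggplot2 visualization helpers for the main result types.

#' Stacked bar chart of clonal bin proportions
#'
#' @param bins Output of [bin_patients()].
#' @return A ggplot object.
#' @export
plot_clonal_bins <- function(bins) {
  check_columns(bins, c("bin"))
  d <- dplyr::count(bins, .data$bin) |>
    dplyr::mutate(fraction = n / sum(n))
  ggplot(d, aes(x = .data$bin, y = .data$fraction, fill = .data$bin)) +
    geom_col(show.legend = FALSE) +
    labs(x = NULL, y = "fraction of patients",
         title = "Clonal evolution bins") +
    theme_minimal()
}

#' Kaplan-Meier curves for a survival comparison
#'
#' @param object An `epiclone_survcmp` object.
#' @param ... Unused.
#' @return A ggplot object with one survival step per clonality group.
#' @exportS3Method ggplot2::autoplot
autoplot.epiclone_survcmp <- function(object, ...) {
  km <- object$km
  groups <- sub("^clonality=", "", rep(names(km$strata), km$strata))
  d <- tibble(time = km$time, surv = km$surv, group = groups)
  d <- dplyr::bind_rows(
    tibble(time = 0, surv = 1, group = unique(groups)), d)
  ggplot(d, aes(x = .data$time, y = .data$surv, color = .data$group)) +
    geom_step() +
    labs(x = "days to relapse", y = "relapse-free fraction",
         color = "clonality",
         subtitle = sprintf("log-rank p = %.3g; Cox HR = %.2f",
                            object$logrank_p, object$hr)) +
    theme_minimal()
}

#' Volcano plot of differential accessibility
#'
#' @param differential Output of [differential_accessibility()].
#' @param alpha `padj` significance line (default 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(differential, alpha = 0.05) {
  check_columns(differential, c("log2fc", "p", "padj"))
  d <- dplyr::filter(differential, !is.na(.data$p)) |>
    dplyr::mutate(signif = !is.na(.data$padj) & .data$padj < alpha)
  ggplot(d, aes(x = .data$log2fc, y = -log10(.data$p),
                color = .data$signif)) +
    geom_point(size = 0.4, alpha = 0.6) +
    geom_vline(xintercept = 0, linetype = 3) +
    labs(x = "log2 fold change (relapse vs diagnosis)",
         y = "-log10 p", color = sprintf("padj < %.2g", alpha)) +
    theme_minimal()
}

#' Heatmap of cluster pseudobulk similarity
#'
#' @param object An `epiclone_cluster_sim` object.
#' @param ... Unused.
#' @return A ggplot tile heatmap ordered by the hierarchical grouping.
#' @exportS3Method ggplot2::autoplot
autoplot.epiclone_cluster_sim <- function(object, ...) {
  ord <- object$hclust$labels[object$hclust$order]
  d <- object$pairs
  d <- dplyr::bind_rows(d, tibble(a = ord, b = ord, r = 1))
  d$a <- factor(d$a, levels = ord)
  d$b <- factor(d$b, levels = ord)
  ggplot(d, aes(x = .data$a, y = .data$b, fill = .data$r)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(min(d$r), 1)) +
    labs(x = NULL, y = NULL, fill = "Pearson r") +
    theme_minimal()
}

#' Boxplot of inter-clone similarity at diagnosis vs relapse
#'
#' @param object An `epiclone_convergence` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.epiclone_convergence <- function(object, ...) {
  ggplot(object$similarity, aes(x = .data$timepoint, y = .data$r)) +
    geom_boxplot(width = 0.5) +
    geom_point(alpha = 0.6) +
    labs(y = "inter-clone pseudobulk Pearson r", x = NULL,
         subtitle = sprintf("unpaired t-test p = %.3g", object$p)) +
    theme_minimal()
}

#' Clone frequency dynamics between timepoints
#'
#' @param freqs Output of [clone_frequencies()].
#' @return A ggplot object (per-clone frequency lines, significant
#'   changes highlighted).
#' @export
plot_clone_frequencies <- function(freqs) {
  check_columns(freqs, c("clone", "freq_diagnosis", "freq_relapse",
                         "significant"))
  d <- tidyr::pivot_longer(freqs, c("freq_diagnosis", "freq_relapse"),
                           names_to = "timepoint", values_to = "frequency",
                           names_prefix = "freq_")
  ggplot(d, aes(x = .data$timepoint, y = .data$frequency,
                group = .data$clone, color = .data$significant)) +
    geom_line() + geom_point() +
    labs(y = "clone frequency", x = NULL, color = "significant change") +
    theme_minimal()
}

#' Embedding scatter colored by a label
#'
#' @param embedding Cells x components matrix (first two columns drawn).
#' @param labels Character vector aligned with the rows.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, labels) {
  d <- tibble(x = embedding[, 1], y = embedding[, 2],
              label = labels)
  ggplot(d, aes(x = .data$x, y = .data$y, color = .data$label)) +
    geom_point(size = 0.6, alpha = 0.7) +
    labs(x = colnames(embedding)[1], y = colnames(embedding)[2],
         color = NULL) +
    theme_minimal()
}
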