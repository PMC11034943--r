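# Readers and writers for the plain-text formats the pipeline consumes:
# 10x-style fragments.tsv, BED peaks, MatrixMarket count matrices with
# features/barcodes index files, GMT gene sets, and TSV tables.

#' Read a 10x-style fragments file
#'
#' Five tab-separated columns without header: chrom, start, end, barcode,
#' duplicate count. Coordinates are 0-based half-open (BED convention).
#'
#' @param path Path to a `fragments.tsv` (optionally gzipped).
#' @return A tibble with columns `chrom`, `start`, `end`, `barcode`, `count`.
#' @export
read_fragments <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "barcode", "count"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      barcode = readr::col_character(),
      count = readr::col_integer()
    ),
    progress = FALSE
  )
}

#' @rdname read_fragments
#' @param fragments A fragments tibble as returned by [read_fragments()].
#' @export
write_fragments <- function(fragments, path) {
  check_columns(fragments, c("chrom", "start", "end", "barcode", "count"))
  readr::write_tsv(fragments, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read/write BED intervals
#'
#' BED3+ with optional `score` and `sample` columns; 0-based half-open.
#'
#' @param path File path.
#' @return A tibble with `chrom`, `start`, `end` and any extra columns
#'   (`name`, `score`, `sample`) present in the file.
#' @export
read_peaks_bed <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  n_fields <- if (length(first) == 0) 3 else length(strsplit(first, "\t")[[1]])
  names_all <- c("chrom", "start", "end", "name", "score", "sample")
  readr::read_tsv(
    path,
    col_names = names_all[seq_len(min(n_fields, 6))],
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
}

#' @rdname read_peaks_bed
#' @param peaks Peak tibble with at least `chrom`, `start`, `end`.
#' @export
write_peaks_bed <- function(peaks, path) {
  check_columns(peaks, c("chrom", "start", "end"))
  cols <- intersect(c("chrom", "start", "end", "name", "score", "sample"),
                    names(peaks))
  readr::write_tsv(peaks[cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read/write a sparse count matrix as MatrixMarket + index TSVs
#'
#' Writes `<prefix>.mtx` together with `<prefix>.features.tsv` and
#' `<prefix>.barcodes.tsv` holding the row and column names, one per line.
#'
#' @param prefix Path prefix (no extension).
#' @return `read_count_matrix()` returns a `dgCMatrix` with dimnames.
#' @export
read_count_matrix <- function(prefix) {
  m <- Matrix::readMM(paste0(prefix, ".mtx"))
  rows <- readr::read_lines(paste0(prefix, ".features.tsv"))
  cols <- readr::read_lines(paste0(prefix, ".barcodes.tsv"))
  dimnames(m) <- list(rows, cols)
  methods::as(m, "CsparseMatrix")
}

#' @rdname read_count_matrix
#' @param counts Matrix (dense or sparse) with dimnames.
#' @export
write_count_matrix <- function(counts, prefix) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry row and column names")
  }
  sp <- methods::as(methods::as(counts, "dMatrix"), "CsparseMatrix")
  Matrix::writeMM(sp, paste0(prefix, ".mtx"))
  readr::write_lines(rownames(counts), paste0(prefix, ".features.tsv"))
  readr::write_lines(colnames(counts), paste0(prefix, ".barcodes.tsv"))
  invisible(prefix)
}

#' Read/write GMT gene sets
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param gene_sets Named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write a simulation output bundle to disk
#'
#' Serializes whichever components a simulation list carries into the
#' plain-text formats downstream stages read back (TSV tables, BED peaks,
#' MatrixMarket matrices, fragments, GMT), and records a JSON manifest with
#' per-file row counts.
#'
#' @param sim A list as returned by the `simulate_*()` generators; recognized
#'   elements: `mutations`, `clinical`, `truth` (data frames), `peaks`,
#'   `samples`, `cells`, `variants` (data frames), `counts`, `peak_counts`,
#'   `alt_fw`, `alt_rev`, `ref_fw`, `ref_rev` (matrices), `fragments`
#'   (fragments tibble), `gene_sets` (named list).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the manifest as a tibble (`file`, `rows`); also written
#'   to `manifest.json` in `dir`.
#' @export
write_fixture_bundle <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list()
  note <- function(file, rows) {
    manifest[[length(manifest) + 1]] <<- tibble(file = file, rows = rows)
  }

  tables <- c("mutations", "clinical", "truth", "samples", "cells", "variants")
  for (nm in intersect(tables, names(sim))) {
    x <- sim[[nm]]
    if (!is.data.frame(x)) next
    f <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(x, f, progress = FALSE)
    note(basename(f), nrow(x))
  }
  if (!is.null(sim$peaks)) {
    f <- file.path(dir, "peaks.bed")
    write_peaks_bed(sim$peaks, f)
    note(basename(f), nrow(sim$peaks))
  }
  mats <- c("counts", "peak_counts", "alt_fw", "alt_rev", "ref_fw", "ref_rev")
  for (nm in intersect(mats, names(sim))) {
    prefix <- file.path(dir, nm)
    write_count_matrix(sim[[nm]], prefix)
    note(paste0(nm, ".mtx"), nrow(sim[[nm]]))
  }
  if (!is.null(sim$fragments)) {
    f <- file.path(dir, "fragments.tsv")
    write_fragments(sim$fragments, f)
    note(basename(f), nrow(sim$fragments))
  }
  if (!is.null(sim$gene_sets)) {
    f <- file.path(dir, "gene_sets.gmt")
    write_gmt(sim$gene_sets, f)
    note(basename(f), length(sim$gene_sets))
  }

  manifest <- dplyr::bind_rows(manifest)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
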