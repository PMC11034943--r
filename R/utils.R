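# Shared internal helpers.

#' Counts-per-million normalization
#'
#' Scales each column (sample or cell) of a counts matrix so that it sums to
#' one million. Columns with zero total are left at zero with a warning.
#'
#' @param counts A numeric matrix or sparse `Matrix` of non-negative counts,
#'   features in rows and samples/cells in columns.
#' @return A matrix of the same shape and class family with columns summing
#'   to 1e6 (up to machine precision) wherever the input column was nonzero.
#' @export
#' @examples
#' m <- matrix(c(1, 3, 2, 2), 2)
#' colSums(cpm_normalize(m))
cpm_normalize <- function(counts) {
  depth <- Matrix::colSums(counts)
  zero <- depth == 0
  if (any(zero)) {
    warn(sprintf("%d column(s) with zero depth left unnormalized", sum(zero)))
    depth[zero] <- 1
  }
  if (inherits(counts, "sparseMatrix")) {
    counts %*% Matrix::Diagonal(x = 1e6 / depth)
  } else {
    sweep(counts, 2, depth / 1e6, "/")
  }
}

# Stop unless a data frame has the named columns.
check_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Derive a generator-local seed from a base seed; keeps results independent
# across generators sharing one config seed while staying < 2^31.
offset_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

# Pearson correlation that signals on zero-variance input instead of
# returning NA silently.
safe_cor <- function(x, y, context = "correlation") {
  if (sd(x) == 0 || sd(y) == 0) {
    abort(sprintf("%s undefined: zero-variance vector", context),
          class = "epiclone_zero_variance")
  }
  cor(x, y)
}

# half-open [start, end) interval overlap on 0-based coordinates
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# Convert 0-based half-open intervals to a GRanges (1-based closed).
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Positions (0-based) to width-1 GRanges.
positions_to_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pos + 1L, width = 1L)
  )
}
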