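#' Relative log expression (median-of-ratios) size factors
#'
#' For each sample j the size factor is the median, over reference
#' promoters, of the ratio of its count to the per-promoter geometric mean
#' across samples. The reference set consists of promoters with strictly
#' positive counts in every sample. Factors are rescaled so their geometric
#' mean is exactly 1, making them pure between-sample composition
#' corrections on top of library size.
#'
#' @param matrix an [expression_matrix()] on the `raw_tags` scale with at
#'   least two samples.
#' @return an object of class `size_factor_set`: a data.frame with columns
#'   `sample_id`, `lib_size` (raw column total) and `size_factor`.
#' @export
rle_size_factors <- function(matrix) {
  validate_expression_matrix(matrix)
  if (matrix$scale != "raw_tags")
    stop("RLE size factors are computed from raw tag counts")
  v <- matrix$values
  if (ncol(v) < 2L) stop("need >= 2 samples for RLE normalization")
  ref <- rowSums(v > 0) == ncol(v)
  if (!any(ref))
    stop("no promoter has positive counts in every sample; ",
         "apply a low-count filter or restrict samples first")
  logv <- log(v[ref, , drop = FALSE])
  ratio <- exp(logv - rowMeans(logv))
  f <- apply(ratio, 2, stats::median)
  f <- f / exp(mean(log(f)))
  structure(
    data.frame(sample_id = colnames(v), lib_size = colSums(v),
               size_factor = f, row.names = NULL),
    class = c("size_factor_set", "data.frame"))
}

#' Convert raw tag counts to tags per million (tpm)
#'
#' `tpm_ij = count_ij * 1e6 / (N_j * f_j)` where `N_j` is the raw library
#' size (column total) and `f_j` the RLE size factor, i.e. normalization is
#' against the effective library size.
#'
#' @param matrix an [expression_matrix()] on the `raw_tags` scale.
#' @param size_factors a [rle_size_factors()] result covering all samples;
#'   `NULL` uses unit factors (plain per-million scaling).
#' @return an [expression_matrix()] on the `tpm` scale.
#' @export
to_tpm <- function(matrix, size_factors = NULL) {
  validate_expression_matrix(matrix)
  if (matrix$scale != "raw_tags") stop("input must be raw tag counts")
  n <- colSums(matrix$values)
  if (any(n == 0)) stop("zero library size in sample(s): ",
                        paste(colnames(matrix$values)[n == 0], collapse = ", "))
  f <- rep(1, ncol(matrix$values))
  if (!is.null(size_factors)) {
    idx <- match(colnames(matrix$values), size_factors$sample_id)
    if (anyNA(idx)) stop("size_factors missing sample(s): ",
                         paste(colnames(matrix$values)[is.na(idx)],
                               collapse = ", "))
    f <- size_factors$size_factor[idx]
  }
  tpm <- sweep(matrix$values, 2, 1e6 / (n * f), `*`)
  expression_matrix(tpm, scale = "tpm", sample_meta = matrix$sample_meta)
}

#' Remove promoters with low counts in any sample
#'
#' Drops every row having fewer than `min_reads` raw tags in at least one
#' sample; row order is preserved. With the default of 10 this is the
#' low-count prefilter applied before differential testing.
#'
#' @param matrix an [expression_matrix()] on the `raw_tags` scale.
#' @param min_reads minimum count required in every sample (default 10).
#' @return the filtered [expression_matrix()] (possibly with zero rows).
#' @export
low_count_filter <- function(matrix, min_reads = 10) {
  validate_expression_matrix(matrix)
  if (matrix$scale != "raw_tags") stop("input must be raw tag counts")
  keep <- rowSums(matrix$values < min_reads) == 0L
  out <- matrix
  out$values <- matrix$values[keep, , drop = FALSE]
  out
}
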