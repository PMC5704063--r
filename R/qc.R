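#' Replicate concordance QC by Spearman rank correlation
#'
#' Computes the Spearman rank correlation of `log2(tpm + 1)` between every
#' pair of samples within each replicate group (ties receive average
#' ranks). A sample fails QC when the median of its correlations with its
#' group co-members falls below `threshold` - the logic used to drop a
#' cultured replicate that has drifted away from its siblings. Singleton
#' groups pass with a warning (the correlation is undefined).
#'
#' @param tpm_matrix an [expression_matrix()] on the `tpm` scale.
#' @param replicate_groups named character vector or factor mapping each
#'   sample ID to its replicate group; samples not listed are ignored.
#' @param threshold minimum acceptable median within-group correlation
#'   (default 0.7).
#' @return an object of class `qc_report`: list with `pairs` (data.frame
#'   `group`, `sample_a`, `sample_b`, `rho`), `samples` (data.frame
#'   `sample_id`, `group`, `median_rho`, `pass`) and `threshold`.
#' @export
replicate_concordance <- function(tpm_matrix, replicate_groups,
                                  threshold = 0.7) {
  validate_expression_matrix(tpm_matrix)
  if (tpm_matrix$scale != "tpm") stop("concordance QC expects tpm values")
  stopifnot(threshold > 0, threshold < 1)
  groups <- as.character(replicate_groups)
  names(groups) <- names(replicate_groups)
  unknown <- setdiff(names(groups), colnames(tpm_matrix$values))
  if (length(unknown))
    stop("replicate_groups references unknown sample(s): ",
         paste(unknown, collapse = ", "))
  logv <- log2(tpm_matrix$values[, names(groups), drop = FALSE] + 1)
  pairs <- NULL
  for (g in unique(groups)) {
    members <- names(groups)[groups == g]
    if (length(members) < 2L) {
      warning("replicate group '", g, "' has a single sample; ",
              "correlation undefined, sample passes")
      next
    }
    cm <- stats::cor(logv[, members, drop = FALSE], method = "spearman")
    idx <- which(upper.tri(cm), arr.ind = TRUE)
    pairs <- rbind(pairs, data.frame(
      group = g, sample_a = members[idx[, 1]], sample_b = members[idx[, 2]],
      rho = cm[idx], stringsAsFactors = FALSE))
  }
  samples <- data.frame(sample_id = names(groups), group = unname(groups),
                        median_rho = NA_real_, pass = TRUE,
                        stringsAsFactors = FALSE)
  if (!is.null(pairs)) {
    for (k in seq_len(nrow(samples))) {
      s <- samples$sample_id[k]
      rhos <- c(pairs$rho[pairs$sample_a == s], pairs$rho[pairs$sample_b == s])
      if (length(rhos)) {
        samples$median_rho[k] <- stats::median(rhos)
        samples$pass[k] <- samples$median_rho[k] >= threshold
      }
    }
  }
  structure(list(pairs = pairs, samples = samples, threshold = threshold),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  n_fail <- sum(!x$samples$pass)
  cat(sprintf("qc_report: %d samples, %d failing (threshold %.2f)\n",
              nrow(x$samples), n_fail, x$threshold))
  if (n_fail)
    cat("  failing:", paste(x$samples$sample_id[!x$samples$pass],
                            collapse = ", "), "\n")
  invisible(x)
}

#' Sanity-check expression of known marker promoters
#'
#' Verifies that a panel of well-established marker promoters for the
#' target cell type is expressed in each sample: a sample fails when any
#' marker falls below `min_tpm`. The comparison uses ">=" semantics, so a
#' marker exactly at `min_tpm` passes.
#'
#' @param tpm_matrix an [expression_matrix()] on the `tpm` scale.
#' @param markers character vector of marker peak IDs; all must be present
#'   in the matrix.
#' @param min_tpm minimum acceptable marker expression (default 10 tpm,
#'   mirroring the screen's target-expression criterion).
#' @param samples samples to check (default: all columns).
#' @return data.frame with columns `sample_id`, `marker`, `tpm`,
#'   `marker_pass`, plus a `sample_pass` flag (all markers pass).
#' @export
marker_panel_check <- function(tpm_matrix, markers, min_tpm = 10,
                               samples = NULL) {
  validate_expression_matrix(tpm_matrix)
  if (tpm_matrix$scale != "tpm") stop("marker check expects tpm values")
  missing <- setdiff(markers, rownames(tpm_matrix$values))
  if (length(missing))
    stop("marker(s) absent from matrix: ", paste(missing, collapse = ", "))
  if (is.null(samples)) samples <- colnames(tpm_matrix$values)
  v <- tpm_matrix$values[markers, samples, drop = FALSE]
  out <- data.frame(
    sample_id = rep(samples, each = length(markers)),
    marker = rep(markers, times = length(samples)),
    tpm = as.vector(v), stringsAsFactors = FALSE)
  out$marker_pass <- out$tpm >= min_tpm
  sample_ok <- tapply(out$marker_pass, out$sample_id, all)
  out$sample_pass <- as.logical(sample_ok[out$sample_id])
  out
}
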