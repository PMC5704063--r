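#' Hierarchical clustering recipes for expression profiles
#'
#' The two agglomerative recipes used by the package's reports:
#' complete linkage on Euclidean distances of `log2(tpm + 1)` profiles
#' (promoter-pattern heatmaps), and average linkage (UPGMA) on Spearman
#' correlation distances `1 - rho` (genome-wide sample similarity).
#' Items with zero rank variance are assigned correlation 0 (distance 1)
#' to any partner. Agglomeration is delegated to [stats::hclust()] and is
#' deterministic for a given input; on tie-free (continuous) data the
#' result is invariant to item order up to relabeling.
#'
#' @param matrix an [expression_matrix()] or plain numeric matrix.
#' @param axis cluster `"rows"` (promoters) or `"columns"` (samples).
#' @param distance `"euclidean_log2"` (Euclidean on `log2(x + 1)`) or
#'   `"spearman"` (`1 - rho`, average ranks for ties; applied to the values
#'   as given).
#' @param linkage `"complete"` or `"average"`.
#' @return an object of class `hclust`: `merge` (n-1 ordered merges),
#'   `height`, `labels`.
#' @export
hierarchical_cluster <- function(matrix,
                                 axis = c("rows", "columns"),
                                 distance = c("euclidean_log2", "spearman"),
                                 linkage = c("complete", "average")) {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  v <- if (inherits(matrix, "ExpressionMatrix")) matrix$values else
    as.matrix(matrix)
  if (axis == "columns") v <- t(v)
  if (nrow(v) < 2L) stop("need >= 2 items to cluster")
  d <- switch(distance,
    euclidean_log2 = stats::dist(log2(v + 1), method = "euclidean"),
    spearman = {
      cm <- suppressWarnings(stats::cor(t(v), method = "spearman"))
      cm[is.na(cm)] <- 0
      diag(cm) <- 1
      stats::as.dist(1 - cm)
    })
  stats::hclust(d, method = linkage)
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k-1 highest merges. Cluster labels are stable: clusters are
#' numbered 1..k by the position of their first leaf in the dendrogram's
#' label order.
#'
#' @param dendrogram an `hclust` object from [hierarchical_cluster()].
#' @param k number of clusters, between 1 and the number of leaves.
#' @return named integer vector mapping each leaf label to its cluster.
#' @export
cut_clusters <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$labels)
  if (length(k) != 1L || is.na(k) || k != round(k) || k < 1 || k > n)
    stop("'k' must be an integer in [1, ", n, "]")
  raw <- stats::cutree(dendrogram, k = k)
  # renumber clusters 1..k by first appearance in label order
  out <- match(raw, unique(raw))
  names(out) <- names(raw)
  storage.mode(out) <- "integer"
  out
}

#' Export screen / differential results as report tables
#'
#' Writes three plain TSV tables: a volcano table (fold change,
#' significance, call, specificity flag per promoter), a cluster-annotated
#' `log2(tpm + 1)` expression table for the clustered promoters, and a run
#' summary of thresholds and counts.
#'
#' @param screen_records data.frame from [specificity_screen()] (may be
#'   `NULL`).
#' @param diff_records data.frame from [differential_expression()] (may be
#'   `NULL`).
#' @param cluster_labels named vector from [cut_clusters()] (may be
#'   `NULL`).
#' @param tpm_matrix an [expression_matrix()] on the `tpm` scale supplying
#'   the expression values of the cluster table.
#' @param dir output directory (created if needed).
#' @param thresholds optional [screen_thresholds()] echoed in the summary.
#' @return invisible character vector of the files written.
#' @export
export_report <- function(screen_records = NULL, diff_records = NULL,
                          cluster_labels = NULL, tpm_matrix = NULL,
                          dir, thresholds = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  volcano_path <- file.path(dir, "volcano.tsv")
  specific_set <- if (!is.null(screen_records))
    screen_records$peak_id[screen_records$specific] else character(0)
  volcano <- if (!is.null(diff_records)) {
    data.frame(peak_id = diff_records$peak_id,
               log2_fc = diff_records$log2_fc,
               neg_log10_adj_p = -log10(pmax(diff_records$adj_p,
                                             .Machine$double.xmin)),
               call = diff_records$call,
               is_specific = diff_records$peak_id %in% specific_set,
               stringsAsFactors = FALSE)
  } else if (!is.null(screen_records)) {
    data.frame(peak_id = screen_records$peak_id,
               log2_fc = screen_records$log2_fc,
               neg_log10_adj_p = -log10(pmax(screen_records$adj_p,
                                             .Machine$double.xmin)),
               call = ifelse(screen_records$specific, "specific", "ns"),
               is_specific = screen_records$specific,
               stringsAsFactors = FALSE)
  } else {
    data.frame(peak_id = character(0), log2_fc = numeric(0),
               neg_log10_adj_p = numeric(0), call = character(0),
               is_specific = logical(0))
  }
  write_results_table(volcano, volcano_path)
  files <- c(files, volcano_path)

  cluster_path <- file.path(dir, "cluster_expression.tsv")
  cluster_tab <- if (!is.null(cluster_labels) && !is.null(tpm_matrix)) {
    peaks <- intersect(names(cluster_labels), rownames(tpm_matrix$values))
    data.frame(peak_id = peaks, cluster = unname(cluster_labels[peaks]),
               log2(tpm_matrix$values[peaks, , drop = FALSE] + 1),
               check.names = FALSE, stringsAsFactors = FALSE,
               row.names = NULL)
  } else {
    data.frame(peak_id = character(0), cluster = integer(0))
  }
  write_results_table(cluster_tab, cluster_path)
  files <- c(files, cluster_path)

  summary_path <- file.path(dir, "run_summary.txt")
  lines <- c(sprintf("promscreen_version: %s",
                     as.character(utils::packageVersion("promscreen"))))
  if (!is.null(thresholds))
    lines <- c(lines, sprintf("threshold_%s: %s", names(thresholds),
                              vapply(thresholds, format, character(1))))
  if (!is.null(screen_records))
    lines <- c(lines,
               sprintf("n_screened: %d", nrow(screen_records)),
               sprintf("n_specific: %d", sum(screen_records$specific)),
               sprintf("n_crit%d_pass: %d", 1:5, vapply(
                 paste0("crit", 1:5),
                 function(cc) sum(screen_records[[cc]]), integer(1))))
  if (!is.null(diff_records))
    lines <- c(lines,
               sprintf("n_tested: %d", nrow(diff_records)),
               sprintf("n_up: %d", sum(diff_records$call == "up")),
               sprintf("n_down: %d", sum(diff_records$call == "down")))
  if (!is.null(cluster_labels))
    lines <- c(lines,
               sprintf("n_clusters: %d", length(unique(cluster_labels))))
  writeLines(lines, summary_path)
  files <- c(files, summary_path)
  invisible(files)
}
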