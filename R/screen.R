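#' Thresholds of the five-criterion specificity screen
#'
#' Defaults are the screen's published constants: every target sample above
#' 10 tpm, reference mean below 3 tpm, reference maximum below the target
#' mean, log2 fold change above 5, and BH-adjusted P below 0.01. All
#' inequalities are strict; boundary values fail.
#'
#' @param min_target_tpm criterion 1: minimum over target samples must
#'   exceed this (tpm).
#' @param max_ref_mean_tpm criterion 2: reference mean must fall below this
#'   (tpm).
#' @param min_log2fc criterion 4: `log2((target_mean + c)/(ref_mean + c))`
#'   must exceed this.
#' @param alpha criterion 5: adjusted p must fall below this.
#' @param fc_pseudocount pseudocount `c` (tpm) used in criterion 4; keeps
#'   the fold change finite when the reference mean is exactly 0.
#' @return a list of class `screen_thresholds`.
#' @export
screen_thresholds <- function(min_target_tpm = 10, max_ref_mean_tpm = 3,
                              min_log2fc = 5, alpha = 0.01,
                              fc_pseudocount = 0.1) {
  stopifnot(min_target_tpm > 0, max_ref_mean_tpm > 0, min_log2fc > 0,
            alpha > 0, fc_pseudocount >= 0)
  structure(list(min_target_tpm = min_target_tpm,
                 max_ref_mean_tpm = max_ref_mean_tpm,
                 min_log2fc = min_log2fc, alpha = alpha,
                 fc_pseudocount = fc_pseudocount),
            class = "screen_thresholds")
}

#' Five-criterion promoter specificity screen
#'
#' Flags promoters specifically expressed in a small target group relative
#' to a large reference atlas. The five criteria are: (1) expression in
#' every target sample above `min_target_tpm`; (2) mean reference
#' expression below `max_ref_mean_tpm`; (3) maximum reference expression
#' below the target mean; (4) `log2((target_mean + c)/(ref_mean + c))`
#' above `min_log2fc`; (5) BH-adjusted p-value of the target-vs-reference
#' count test below `alpha`. A promoter is specific iff all five hold.
#'
#' @param tpm_matrix an [expression_matrix()] on the `tpm` scale.
#' @param target_samples,reference_samples disjoint, non-empty sample ID
#'   sets.
#' @param p_values named vector of raw p-values (one per promoter of the
#'   matrix) from [nb_exact_test()] on the same target-vs-reference
#'   comparison; adjusted internally with [bh_adjust()].
#' @param thresholds a [screen_thresholds()] object.
#' @return a data.frame of screen records: `peak_id`, `target_min`,
#'   `target_mean`, `ref_mean`, `ref_max`, `log2_fc`, `p`, `adj_p`,
#'   `crit1`..`crit5`, `specific`.
#' @export
specificity_screen <- function(tpm_matrix, target_samples, reference_samples,
                               p_values, thresholds = screen_thresholds()) {
  validate_expression_matrix(tpm_matrix)
  if (tpm_matrix$scale != "tpm") stop("the screen operates on tpm values")
  stopifnot(inherits(thresholds, "screen_thresholds"))
  if (!length(target_samples) || !length(reference_samples))
    stop("target and reference sample sets must be non-empty")
  if (length(intersect(target_samples, reference_samples)))
    stop("target and reference sample sets overlap: ",
         paste(intersect(target_samples, reference_samples), collapse = ", "))
  bad <- setdiff(c(target_samples, reference_samples),
                 colnames(tpm_matrix$values))
  if (length(bad)) stop("unknown sample(s): ", paste(bad, collapse = ", "))
  ids <- rownames(tpm_matrix$values)
  missing_p <- setdiff(ids, names(p_values))
  if (length(missing_p))
    stop("p_values missing promoter(s): ",
         paste(utils::head(missing_p, 5), collapse = ", "),
         if (length(missing_p) > 5) ", ...")
  p <- unname(p_values[ids])
  adj_p <- bh_adjust(p)

  tv <- tpm_matrix$values[, target_samples, drop = FALSE]
  rv <- tpm_matrix$values[, reference_samples, drop = FALSE]
  target_min <- apply(tv, 1, min)
  target_mean <- rowMeans(tv)
  ref_mean <- rowMeans(rv)
  ref_max <- apply(rv, 1, max)
  c0 <- thresholds$fc_pseudocount
  log2_fc <- log2((target_mean + c0) / (ref_mean + c0))

  rec <- data.frame(
    peak_id = ids, target_min = target_min, target_mean = target_mean,
    ref_mean = ref_mean, ref_max = ref_max, log2_fc = log2_fc,
    p = p, adj_p = adj_p,
    crit1 = target_min > thresholds$min_target_tpm,
    crit2 = ref_mean < thresholds$max_ref_mean_tpm,
    crit3 = ref_max < target_mean,
    crit4 = log2_fc > thresholds$min_log2fc,
    crit5 = adj_p < thresholds$alpha,
    stringsAsFactors = FALSE, row.names = NULL)
  rec$specific <- rec$crit1 & rec$crit2 & rec$crit3 & rec$crit4 & rec$crit5
  attr(rec, "thresholds") <- thresholds
  rec
}

#' Intersect two specificity screens
#'
#' @param records_a,records_b screen record data.frames from
#'   [specificity_screen()] (e.g. the tissue and primary-cell facets).
#' @return character vector of peak IDs specific in both screens.
#' @export
intersect_screens <- function(records_a, records_b) {
  stopifnot(is.data.frame(records_a), is.data.frame(records_b),
            all(c("peak_id", "specific") %in% names(records_a)),
            all(c("peak_id", "specific") %in% names(records_b)))
  intersect(records_a$peak_id[records_a$specific],
            records_b$peak_id[records_b$specific])
}

#' Collapse a promoter set to gene loci
#'
#' Groups peaks by their gene symbol; peaks without a gene mapping form
#' singleton loci keyed by their own (location-style) ID. Within a locus
#' promoters are sorted by rank (unranked last).
#'
#' @param peaks character vector of peak IDs.
#' @param promoter_records data.frame with at least `peak_id`,
#'   `gene_symbol` and `rank` (e.g. from [assign_promoter_ranks()] or
#'   [parse_promoter_id()]).
#' @return named list: one element per locus, each a character vector of
#'   its peak IDs sorted by rank.
#' @export
collapse_to_loci <- function(peaks, promoter_records) {
  stopifnot(is.character(peaks),
            all(c("peak_id", "gene_symbol") %in% names(promoter_records)))
  idx <- match(peaks, promoter_records$peak_id)
  gene <- promoter_records$gene_symbol[idx]
  rank <- if ("rank" %in% names(promoter_records))
    promoter_records$rank[idx] else rep(NA_integer_, length(peaks))
  locus <- ifelse(is.na(gene), peaks, gene)
  out <- lapply(split(seq_along(peaks), locus), function(i)
    peaks[i][order(rank[i], peaks[i], na.last = TRUE)])
  out[order(names(out))]
}

#' Classify a gene's specificity as major- or alternative-promoter driven
#'
#' A gene whose main promoter (p1) is itself specific - or whose p1 is
#' simply silent in the reference atlas - is `major_promoter_specific`.
#' When p1 is not among the gene's specific promoters *and* is broadly
#' expressed in the reference (maximum reference tpm at or above
#' `broad_tpm_threshold`), the specificity is carried only by an
#' alternative promoter and the gene is classified
#' `alternative_promoter_only` - the exclusion pattern where a non-major
#' promoter is target-specific while the gene's main promoter is active in
#' many other tissues or cells.
#'
#' @param gene gene symbol (must have at least one specific promoter).
#' @param screen_records data.frame from [specificity_screen()].
#' @param tpm_matrix an [expression_matrix()] on the `tpm` scale containing
#'   the gene's p1.
#' @param promoter_records data.frame mapping `peak_id` to `gene_symbol`
#'   and `rank`.
#' @param reference_samples sample IDs of the reference atlas.
#' @param broad_tpm_threshold reference tpm at which p1 counts as broadly
#'   expressed (default 10, mirroring the screen's criterion 1).
#' @return list of class `gene_specificity_call`: `gene_symbol`,
#'   `specific_promoters`, `category`, `p1_peak`, `p1_ref_max`.
#' @export
classify_gene_specificity <- function(gene, screen_records, tpm_matrix,
                                      promoter_records, reference_samples,
                                      broad_tpm_threshold = 10) {
  validate_expression_matrix(tpm_matrix)
  stopifnot(all(c("peak_id", "gene_symbol", "rank") %in%
                  names(promoter_records)))
  gene_peaks <- promoter_records$peak_id[
    !is.na(promoter_records$gene_symbol) &
      promoter_records$gene_symbol == gene]
  specific <- intersect(
    screen_records$peak_id[screen_records$specific], gene_peaks)
  if (!length(specific))
    stop("gene ", gene, " has no specific promoter")
  p1 <- promoter_records$peak_id[
    !is.na(promoter_records$gene_symbol) &
      promoter_records$gene_symbol == gene &
      !is.na(promoter_records$rank) & promoter_records$rank == 1L]
  if (!length(p1))
    stop("gene ", gene, " has no ranked p1 promoter")
  if (!p1 %in% rownames(tpm_matrix$values))
    stop("p1 promoter ", p1, " absent from the expression matrix")
  p1_ref_max <- max(tpm_matrix$values[p1, reference_samples])
  category <- if (!(p1 %in% specific) && p1_ref_max >= broad_tpm_threshold)
    "alternative_promoter_only" else "major_promoter_specific"
  structure(list(gene_symbol = gene, specific_promoters = specific,
                 category = category, p1_peak = p1, p1_ref_max = p1_ref_max),
            class = "gene_specificity_call")
}

#' Overlap of a specific promoter set with differential calls
#'
#' @param specific_peaks non-empty character vector of specific peak IDs.
#' @param diff_records data.frame from [differential_expression()]; peaks
#'   of the specific set missing from it are counted as `ns` with a
#'   warning.
#' @return list `n_up`, `n_down`, `n_total`, `frac_up`.
#' @export
overlap_with_differential <- function(specific_peaks, diff_records) {
  if (!length(specific_peaks)) stop("empty specific set")
  stopifnot(all(c("peak_id", "call") %in% names(diff_records)))
  calls <- diff_records$call[match(specific_peaks, diff_records$peak_id)]
  if (anyNA(calls)) {
    warning(sum(is.na(calls)),
            " specific peak(s) missing from differential records; ",
            "counted as ns")
    calls[is.na(calls)] <- "ns"
  }
  n_up <- sum(calls == "up")
  n_down <- sum(calls == "down")
  list(n_up = n_up, n_down = n_down, n_total = length(specific_peaks),
       frac_up = n_up / length(specific_peaks))
}

#' Hypergeometric over-representation test for gene categories
#'
#' One-sided hypergeometric tail probability that a selected gene set
#' overlaps each category at least as much as observed, BH-adjusted across
#' categories. A generic stand-in for annotation-database enrichment tools:
#' category gene sets are supplied by the caller.
#'
#' @param selected character vector of selected genes (subset of
#'   `universe`).
#' @param categories named list of character vectors (category -> genes);
#'   genes outside `universe` are ignored.
#' @param universe character vector: the gene universe.
#' @return data.frame `category`, `n_category`, `n_overlap`, `p`, `adj_p`,
#'   sorted by `p`.
#' @export
enrichment_test <- function(selected, categories, universe) {
  universe <- unique(universe)
  selected <- unique(selected)
  if (length(setdiff(selected, universe)))
    stop("selected genes outside the universe: ",
         paste(utils::head(setdiff(selected, universe), 5), collapse = ", "))
  stopifnot(is.list(categories), !is.null(names(categories)))
  n <- length(universe)
  k <- length(selected)
  rows <- lapply(names(categories), function(cat) {
    members <- intersect(unique(categories[[cat]]), universe)
    q <- length(intersect(selected, members))
    data.frame(category = cat, n_category = length(members), n_overlap = q,
               p = stats::phyper(q - 1, length(members),
                                 n - length(members), k, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out[order(out$p, out$category), , drop = FALSE]
}
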