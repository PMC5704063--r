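#' Parse CAGE peak (promoter) identifiers
#'
#' Understands the three FANTOM5-style forms: `p<k>@<GENE>` (ranked,
#' gene-associated, e.g. `p1@PITX2`), `p@<chrom>:<a>..<b>,<strand>`
#' (unranked, location-only), and `p<k>@<chrom>:<a>..<b>,<strand>`.
#' Genomic spans are stored 0-based half-open, following the BED-derived
#' peak-name convention. Promoters ranked p1-p3 are flagged as major
#' promoters.
#'
#' @param peak_id character vector of peak identifiers.
#' @return a data.frame of promoter records with columns `peak_id`,
#'   `gene_symbol`, `chrom`, `start`, `end`, `strand`, `rank`, `is_major`.
#' @export
parse_promoter_id <- function(peak_id) {
  stopifnot(is.character(peak_id))
  m <- regmatches(peak_id, regexec("^p([0-9]+)?@(.+)$", peak_id))
  bad <- lengths(m) == 0L
  if (any(bad))
    stop("unrecognized peak identifier(s): ",
         paste(peak_id[bad], collapse = ", "))
  rank <- vapply(m, function(x)
    if (nzchar(x[2])) as.integer(x[2]) else NA_integer_, integer(1))
  if (any(!is.na(rank) & rank < 1L))
    stop("promoter rank must be >= 1 in: ",
         paste(peak_id[!is.na(rank) & rank < 1L], collapse = ", "))
  payload <- vapply(m, `[[`, character(1), 3L)
  loc <- regmatches(payload,
                    regexec("^([^:]+):([0-9]+)\\.\\.([0-9]+),([+-])$", payload))
  is_loc <- lengths(loc) == 5L
  rec <- data.frame(
    peak_id = peak_id,
    gene_symbol = ifelse(is_loc, NA_character_, payload),
    chrom = NA_character_, start = NA_integer_, end = NA_integer_,
    strand = NA_character_,
    rank = rank,
    stringsAsFactors = FALSE)
  if (any(is_loc)) {
    locm <- do.call(rbind, loc[is_loc])
    rec$chrom[is_loc] <- locm[, 2]
    rec$start[is_loc] <- as.integer(locm[, 3])
    rec$end[is_loc] <- as.integer(locm[, 4])
    rec$strand[is_loc] <- locm[, 5]
    if (any(rec$end[is_loc] <= rec$start[is_loc]))
      stop("peak span end must exceed start in: ",
           paste(peak_id[is_loc][rec$end[is_loc] <= rec$start[is_loc]],
                 collapse = ", "))
  }
  rec$is_major <- !is.na(rec$rank) & rec$rank <= 3L
  rec
}

#' Rank promoters within gene loci by total tag count
#'
#' Within each gene, promoters are labeled p1, p2, ... in order of
#' decreasing total raw tag count over all samples; p1-p3 are flagged
#' major. Ties are broken by ascending genomic start (when known), then by
#' lexicographic peak ID. Promoters not mapped to any gene receive no rank.
#'
#' @param matrix an [expression_matrix()] on the `raw_tags` scale.
#' @param gene_map data.frame with columns `peak_id` and `gene_symbol`
#'   mapping each promoter to at most one gene (`NA` = unmapped).
#' @return a data.frame of promoter records as in [parse_promoter_id()],
#'   with `rank`/`is_major` assigned from the tag totals and an added
#'   `total_tags` column.
#' @export
assign_promoter_ranks <- function(matrix, gene_map) {
  validate_expression_matrix(matrix)
  if (matrix$scale != "raw_tags")
    stop("promoter ranking requires raw tag counts")
  stopifnot(is.data.frame(gene_map),
            all(c("peak_id", "gene_symbol") %in% names(gene_map)))
  if (anyDuplicated(gene_map$peak_id))
    stop("gene_map assigns some promoters to more than one gene")
  ids <- rownames(matrix$values)
  rec <- tryCatch(parse_promoter_id(ids),
                  error = function(e) data.frame(
                    peak_id = ids, gene_symbol = NA_character_,
                    chrom = NA_character_, start = NA_integer_,
                    end = NA_integer_, strand = NA_character_,
                    rank = NA_integer_, is_major = FALSE,
                    stringsAsFactors = FALSE))
  rec$gene_symbol <- gene_map$gene_symbol[match(ids, gene_map$peak_id)]
  rec$total_tags <- rowSums(matrix$values)
  rec$rank <- NA_integer_
  mapped <- which(!is.na(rec$gene_symbol))
  for (idx in split(mapped, rec$gene_symbol[mapped])) {
    ord <- order(-rec$total_tags[idx],
                 rec$start[idx], rec$peak_id[idx], method = "radix")
    rec$rank[idx[ord]] <- seq_along(idx)
  }
  rec$is_major <- !is.na(rec$rank) & rec$rank <= 3L
  rec
}

#' Merge technical (lane-level) replicates by summing raw tag counts
#'
#' Raw counts generated from duplicated sequencing of the same library are
#' summed per promoter; each merged sample keeps the metadata of its first
#' lane.
#'
#' @param matrix an [expression_matrix()] on the `raw_tags` scale whose
#'   columns are sequencing lanes.
#' @param lane_map data.frame with columns `lane_id` and `sample_id`
#'   partitioning the columns of `matrix` into samples.
#' @return an [expression_matrix()] with one column per sample.
#' @export
merge_technical_replicates <- function(matrix, lane_map) {
  validate_expression_matrix(matrix)
  if (matrix$scale != "raw_tags")
    stop("technical replicate merging requires raw tag counts")
  stopifnot(is.data.frame(lane_map),
            all(c("lane_id", "sample_id") %in% names(lane_map)))
  unknown <- setdiff(lane_map$lane_id, colnames(matrix$values))
  if (length(unknown))
    stop("lane_map references unknown column(s): ",
         paste(unknown, collapse = ", "))
  unmapped <- setdiff(colnames(matrix$values), lane_map$lane_id)
  if (length(unmapped))
    stop("columns not covered by lane_map: ", paste(unmapped, collapse = ", "))
  sample_of <- lane_map$sample_id[match(colnames(matrix$values),
                                        lane_map$lane_id)]
  samples <- unique(sample_of)
  merged <- vapply(samples, function(s)
    rowSums(matrix$values[, sample_of == s, drop = FALSE]),
    numeric(nrow(matrix$values)))
  dimnames(merged) <- list(rownames(matrix$values), samples)
  first_lane <- colnames(matrix$values)[match(samples, sample_of)]
  meta <- matrix$sample_meta[match(first_lane, matrix$sample_meta$sample_id), ]
  meta$sample_id <- samples
  expression_matrix(merged, scale = "raw_tags", sample_meta = meta)
}
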