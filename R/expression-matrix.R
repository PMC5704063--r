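#' Construct a promoter expression matrix
#'
#' The central container of the package: a promoter-by-sample matrix of
#' non-negative CAGE tag counts (`scale = "raw_tags"`) or normalized
#' tags-per-million values (`scale = "tpm"`), together with per-sample
#' metadata.
#'
#' @param values numeric matrix, promoters in rows, samples in columns.
#'   Row names are promoter (CAGE peak) IDs, column names are sample IDs;
#'   both must be unique. Raw tag counts must be non-negative integers.
#' @param scale `"raw_tags"` or `"tpm"`.
#' @param sample_meta optional data.frame with one row per sample and columns
#'   `sample_id`, `group`, `facet`, `donor_id`, `replicate_id`. Samples
#'   present in `values` but absent here are filled in with
#'   `facet = "unspecified"` and missing donor/replicate. The screen
#'   convention uses `group` values `"target"` and `"reference"`; the paired
#'   differentiation design uses its own state labels.
#'
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values`, `scale` and `sample_meta`.
#' @export
expression_matrix <- function(values, scale = c("raw_tags", "tpm"),
                              sample_meta = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have promoter row names and sample column names")
  obj <- structure(
    list(values = values, scale = scale,
         sample_meta = complete_sample_meta(sample_meta, colnames(values))),
    class = "ExpressionMatrix")
  validate_expression_matrix(obj)
  obj
}

META_COLUMNS <- c("sample_id", "group", "facet", "donor_id", "replicate_id")

complete_sample_meta <- function(sample_meta, sample_ids) {
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = character(0))
  }
  if (!is.data.frame(sample_meta) || !"sample_id" %in% names(sample_meta))
    stop("'sample_meta' must be a data.frame with a 'sample_id' column")
  for (col in setdiff(META_COLUMNS, names(sample_meta)))
    sample_meta[[col]] <- rep(NA_character_, nrow(sample_meta))
  sample_meta <- sample_meta[META_COLUMNS]
  if (anyDuplicated(sample_meta$sample_id))
    stop("duplicate sample_id in sample_meta: ",
         paste(unique(sample_meta$sample_id[duplicated(sample_meta$sample_id)]),
               collapse = ", "))
  missing <- setdiff(sample_ids, sample_meta$sample_id)
  if (length(missing)) {
    add <- data.frame(sample_id = missing, group = NA_character_,
                      facet = "unspecified", donor_id = NA_character_,
                      replicate_id = NA_character_)
    sample_meta <- rbind(sample_meta, add)
  }
  sample_meta <- sample_meta[match(sample_ids, sample_meta$sample_id), ]
  sample_meta$facet[is.na(sample_meta$facet)] <- "unspecified"
  bad <- !sample_meta$facet %in% c("tissue", "primary_cell", "unspecified")
  if (any(bad))
    stop("unknown facet value(s): ",
         paste(unique(sample_meta$facet[bad]), collapse = ", "))
  rownames(sample_meta) <- NULL
  sample_meta
}

validate_expression_matrix <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  if (anyDuplicated(rownames(v)))
    stop("duplicate promoter_id: ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  if (anyDuplicated(colnames(v)))
    stop("duplicate sample_id: ",
         paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "))
  if (anyNA(v)) stop("expression values must not be NA")
  if (any(v < 0)) stop("expression values must be non-negative")
  if (x$scale == "raw_tags" && any(v != round(v)))
    stop("raw_tags values must be integers")
  if (!identical(x$sample_meta$sample_id, colnames(v)))
    stop("sample_meta rows must match matrix columns")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d promoters x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  groups <- table(x$sample_meta$group, useNA = "ifany")
  cat("  groups:", paste(sprintf("%s=%d", names(groups), groups),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Subset an ExpressionMatrix
#'
#' @param x an [expression_matrix()].
#' @param i,j promoter and sample indices (any form accepted by matrix
#'   subsetting).
#' @param ... ignored.
#' @return an `ExpressionMatrix` restricted to the selected promoters/samples.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  expression_matrix(v, scale = x$scale,
                    sample_meta = x$sample_meta[
                      match(colnames(v), x$sample_meta$sample_id), ,
                      drop = FALSE])
}

#' Read a FANTOM5-style promoter expression table
#'
#' Reads a tab-delimited table whose first column is the CAGE peak
#' (promoter) ID and whose remaining columns are samples. Lines starting
#' with `##` are treated as comments. Sample metadata is joined from a
#' second table; samples without metadata get `facet = "unspecified"`.
#'
#' @param path path to the expression table.
#' @param meta_path optional path to a sample metadata table (tab-delimited,
#'   columns `sample_id`, `group`, `facet`, `donor_id`, `replicate_id`).
#' @param scale declared scale of the values, `"raw_tags"` or `"tpm"`.
#' @return an [expression_matrix()].
#' @export
read_expression_table <- function(path, meta_path = NULL,
                                  scale = c("raw_tags", "tpm")) {
  scale <- match.arg(scale)
  lines <- readLines(path)
  keep <- !startsWith(lines, "##") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 1L) stop("no header line in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncol_expected <- length(header)
  if (ncol_expected < 2L) stop("expression table needs >= 2 columns")
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != ncol_expected)) {
    bad <- which(widths != ncol_expected)[1]
    stop(sprintf("malformed row at line %d: %d fields, expected %d",
                 line_no[bad + 1L], widths[bad], ncol_expected))
  }
  ids <- vapply(body, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = ncol_expected - 1L,
                 dimnames = list(ids, header[-1]))
  for (k in seq_along(body)) {
    row <- suppressWarnings(as.numeric(body[[k]][-1]))
    if (anyNA(row))
      stop(sprintf("non-numeric value at line %d (promoter %s)",
                   line_no[k + 1L], ids[k]))
    vals[k, ] <- row
  }
  meta <- if (!is.null(meta_path)) {
    utils::read.delim(meta_path, stringsAsFactors = FALSE,
                      colClasses = "character")
  }
  expression_matrix(vals, scale = scale, sample_meta = meta)
}

#' Write a result table as plain TSV
#'
#' Deterministic column order (as given), one header row, tab-delimited;
#' numeric columns are formatted at 6 significant digits unless
#' `digits = NA` (full precision, used for re-readable expression values).
#'
#' @param records a data.frame of results (screen records, differential
#'   records, promoter records, ...).
#' @param path output path.
#' @param digits significant digits for numeric columns; `NA` keeps full
#'   (up to 15-digit) precision.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path, digits = 6) {
  stopifnot(is.data.frame(records))
  out <- records
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- formatC(out[[col]],
                            digits = if (is.na(digits)) 15 else digits,
                            format = "g")
      out[[col]][out[[col]] %in% c("NA", " NA")] <- "NA"
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write an ExpressionMatrix as a FANTOM5-style TSV
#'
#' Values are written at full precision so that
#' [read_expression_table()] round-trips them to at least 12 significant
#' digits.
#'
#' @param matrix an [expression_matrix()].
#' @param path output path for the expression table.
#' @param meta_path optional output path for the sample metadata table.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(matrix, path, meta_path = NULL) {
  validate_expression_matrix(matrix)
  df <- data.frame(peak_id = rownames(matrix$values),
                   signif(matrix$values, 15), check.names = FALSE)
  write_results_table(df, path, digits = NA)
  if (!is.null(meta_path))
    utils::write.table(matrix$sample_meta, meta_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
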