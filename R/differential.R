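#' Differential promoter expression between two sample groups
#'
#' Significance comes from the negative-binomial exact test on raw counts
#' (group A vs group B) with Benjamini-Hochberg correction; effect size
#' comes from tpm fold changes. In `paired` mode the two groups must
#' contain the same donors (matched via `donor_id` in the sample metadata)
#' and the reported `mean_fc` is the geometric mean over donors of
#' `(tpm_B,d + c) / (tpm_A,d + c)` - symmetric under direction reversal;
#' an arithmetic mean is available via `fc_mean`. A promoter is called
#' `up` when `mean_fc > fc_threshold` and `adj_p < alpha`, `down` when
#' `mean_fc < 1 / fc_threshold` and `adj_p < alpha`, otherwise `ns`.
#'
#' @param tpm_matrix an [expression_matrix()] on the `tpm` scale.
#' @param count_matrix the matching [expression_matrix()] of raw tags
#'   (same promoters and samples).
#' @param group_a,group_b character vectors of sample IDs.
#' @param mode `"paired"` (donor-matched) or `"unpaired"`.
#' @param fc_threshold fold-change cutoff for a call (default 2).
#' @param alpha adjusted-p cutoff for a call (default 0.01).
#' @param pseudocount tpm pseudocount `c` added to both sides of every fold
#'   change (default 1 tpm; tames zero denominators).
#' @param phi NB dispersion; `NULL` estimates it with
#'   [estimate_common_dispersion()] on the two groups.
#' @param size_factors optional [rle_size_factors()] result used for the
#'   effective library sizes of the exact test.
#' @param fc_mean `"geometric"` or `"arithmetic"` mean of per-donor fold
#'   changes (paired mode only).
#' @return a data.frame of differential records: `peak_id`, `mean_a`,
#'   `mean_b` (group mean tpm), per-donor fold-change columns `fc_<donor>`
#'   in paired mode, `mean_fc`, `log2_fc`, `p`, `adj_p`, `call`, plus a
#'   `phi` attribute.
#' @export
differential_expression <- function(tpm_matrix, count_matrix,
                                    group_a, group_b,
                                    mode = c("paired", "unpaired"),
                                    fc_threshold = 2, alpha = 0.01,
                                    pseudocount = 1, phi = NULL,
                                    size_factors = NULL,
                                    fc_mean = c("geometric", "arithmetic")) {
  mode <- match.arg(mode)
  fc_mean <- match.arg(fc_mean)
  validate_expression_matrix(tpm_matrix)
  validate_expression_matrix(count_matrix)
  if (tpm_matrix$scale != "tpm" || count_matrix$scale != "raw_tags")
    stop("need a tpm matrix and a raw_tags matrix")
  if (!identical(rownames(tpm_matrix$values), rownames(count_matrix$values)))
    stop("tpm and count matrices must cover the same promoters in order")
  all_samples <- colnames(count_matrix$values)
  bad <- setdiff(c(group_a, group_b), all_samples)
  if (length(bad)) stop("unknown sample(s): ", paste(bad, collapse = ", "))
  if (length(intersect(group_a, group_b)))
    stop("group_a and group_b overlap")

  donors <- NULL
  if (mode == "paired") {
    meta <- count_matrix$sample_meta
    donor_of <- function(ids) meta$donor_id[match(ids, meta$sample_id)]
    da <- donor_of(group_a)
    db <- donor_of(group_b)
    if (anyNA(da) || anyNA(db))
      stop("paired mode requires donor_id for every sample")
    unmatched <- c(setdiff(da, db), setdiff(db, da))
    if (length(unmatched) || anyDuplicated(da) || anyDuplicated(db))
      stop("donors not matched one-to-one across groups: ",
           paste(unique(c(unmatched, da[duplicated(da)], db[duplicated(db)])),
                 collapse = ", "))
    donors <- sort(unique(da))
    group_a <- group_a[match(donors, da)]
    group_b <- group_b[match(donors, db)]
  }

  eff <- test_scaling_factors(count_matrix, size_factors)
  names(eff) <- all_samples
  if (is.null(phi)) {
    grp <- rep(NA_character_, length(all_samples))
    grp[all_samples %in% group_a] <- "A"
    grp[all_samples %in% group_b] <- "B"
    phi <- estimate_common_dispersion(count_matrix, grp, size_factors)$phi
  }
  p <- nb_exact_test(count_matrix$values[, group_a, drop = FALSE],
                     count_matrix$values[, group_b, drop = FALSE],
                     phi = phi,
                     eff_lib_a = eff[group_a], eff_lib_b = eff[group_b])
  adj_p <- bh_adjust(p)

  tpm_a <- tpm_matrix$values[, group_a, drop = FALSE]
  tpm_b <- tpm_matrix$values[, group_b, drop = FALSE]
  rec <- data.frame(peak_id = rownames(tpm_matrix$values),
                    mean_a = rowMeans(tpm_a), mean_b = rowMeans(tpm_b),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (mode == "paired") {
    fc <- (tpm_b + pseudocount) / (tpm_a + pseudocount)
    colnames(fc) <- paste0("fc_", donors)
    rec <- cbind(rec, as.data.frame(fc, row.names = NULL))
    rec$mean_fc <- if (fc_mean == "geometric") exp(rowMeans(log(fc)))
                   else rowMeans(fc)
  } else {
    rec$mean_fc <- (rec$mean_b + pseudocount) / (rec$mean_a + pseudocount)
  }
  rec$log2_fc <- log2(rec$mean_fc)
  rec$p <- p
  rec$adj_p <- adj_p
  rec$call <- "ns"
  rec$call[rec$mean_fc > fc_threshold & adj_p < alpha] <- "up"
  rec$call[rec$mean_fc < 1 / fc_threshold & adj_p < alpha] <- "down"
  attr(rec, "phi") <- phi
  rec
}
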