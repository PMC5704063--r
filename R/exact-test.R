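#' Pooled method-of-moments estimate of the common NB dispersion
#'
#' The negative binomial is parameterized throughout the package as
#' `variance = mu + phi * mu^2` (`phi = 0` recovers the Poisson). For each
#' promoter, counts are first brought to a common effective library size;
#' within every group with at least two samples the moment estimate
#' `phi = (s^2 - m) / m^2` is formed from the group mean `m` and unbiased
#' variance `s^2`, and estimates are pooled across groups weighted by
#' residual degrees of freedom. The common dispersion is the median of the
#' per-promoter estimates (floored at 0) over promoters with positive mean.
#'
#' @param matrix an [expression_matrix()] on the `raw_tags` scale.
#' @param groups factor or character vector (length = samples) assigning
#'   each sample to a group; `NA` samples are ignored.
#' @param size_factors optional [rle_size_factors()] result; `NULL` uses
#'   unit factors.
#' @return list with elements `phi` (common dispersion) and
#'   `n_promoters_used`.
#' @export
estimate_common_dispersion <- function(matrix, groups, size_factors = NULL) {
  validate_expression_matrix(matrix)
  if (matrix$scale != "raw_tags") stop("dispersion is estimated from counts")
  groups <- as.character(groups)
  if (length(groups) != ncol(matrix$values))
    stop("'groups' must have one entry per sample")
  use <- !is.na(groups)
  sizes <- table(groups[use])
  if (all(sizes < 2L))
    stop("all groups are singletons; supply an explicit dispersion instead")
  eff <- test_scaling_factors(matrix, size_factors)
  z <- sweep(matrix$values, 2, exp(mean(log(eff[use]))) / eff, `*`)
  num <- 0
  den <- 0
  m_all <- 0
  n_all <- 0
  for (g in names(sizes)[sizes >= 2L]) {
    zg <- z[, use & groups == g, drop = FALSE]
    m <- rowMeans(zg)
    v <- apply(zg, 1, stats::var)
    w <- ncol(zg) - 1L
    phi_g <- ifelse(m > 0, (v - m) / m^2, NA_real_)
    num <- num + ifelse(is.na(phi_g), 0, w * phi_g)
    den <- den + ifelse(is.na(phi_g), 0, w)
    m_all <- m_all + ncol(zg) * m
    n_all <- n_all + ncol(zg)
  }
  usable <- den > 0 & (m_all / n_all) > 0
  phi_i <- pmax(0, num[usable] / den[usable])
  list(phi = max(0, stats::median(phi_i)), n_promoters_used = sum(usable))
}

# per-sample scaling used to equalize counts for testing: the RLE factor
# f_j is itself the full depth-plus-composition correction (median ratio
# of raw counts), so it is used alone; without size factors, plain
# library sizes stand in
test_scaling_factors <- function(matrix, size_factors = NULL) {
  if (is.null(size_factors)) return(colSums(matrix$values))
  idx <- match(colnames(matrix$values), size_factors$sample_id)
  if (anyNA(idx))
    stop("size_factors missing sample(s): ",
         paste(colnames(matrix$values)[is.na(idx)], collapse = ", "))
  size_factors$size_factor[idx]
}

#' Negative-binomial exact test for a two-group count comparison
#'
#' An exact test in the Robinson-Smyth style: counts are scaled to a common
#' effective library size and rounded to pseudo-counts (nearest integer,
#' ties to even), then summed within groups. Conditional on the total
#' `s = y_A + y_B`, the group sums are modeled as independent negative
#' binomials with means `s * n_A / (n_A + n_B)` and `s * n_B / (n_A + n_B)`
#' and dispersions `phi / n_A`, `phi / n_B`; the two-sided p-value is the
#' total conditional probability of all splits no more likely than the one
#' observed. At `phi = 0` the conditional law is exactly
#' `Binomial(s, n_A / (n_A + n_B))`. A total of zero returns p = 1 by
#' convention. Splits are deemed "no more likely" up to a relative
#' probability tolerance of 1e-8, which makes tied outcomes (e.g. the
#' symmetric balanced split) robust to floating-point rounding.
#'
#' @param counts_a,counts_b non-negative integer count matrices (promoters
#'   x samples) for the two groups, or vectors for a single promoter.
#' @param phi NB dispersion (>= 0).
#' @param eff_lib_a,eff_lib_b per-sample scalings proportional to
#'   effective sequencing depth: plain library sizes, or RLE size factors
#'   (which already encode depth). Only ratios matter. Default: column
#'   totals of the supplied counts.
#' @return numeric vector of p-values in (0, 1], one per promoter.
#' @export
nb_exact_test <- function(counts_a, counts_b, phi,
                          eff_lib_a = NULL, eff_lib_b = NULL) {
  if (is.null(dim(counts_a))) counts_a <- matrix(counts_a, nrow = 1)
  if (is.null(dim(counts_b))) counts_b <- matrix(counts_b, nrow = 1)
  if (nrow(counts_a) != nrow(counts_b))
    stop("count matrices must cover the same promoters")
  if (any(counts_a < 0) || any(counts_b < 0) ||
      any(counts_a != round(counts_a)) || any(counts_b != round(counts_b)))
    stop("counts must be non-negative integers")
  if (length(phi) != 1L || is.na(phi) || phi < 0)
    stop("'phi' must be a single non-negative number")
  if (is.null(eff_lib_a)) eff_lib_a <- colSums(counts_a)
  if (is.null(eff_lib_b)) eff_lib_b <- colSums(counts_b)
  stopifnot(length(eff_lib_a) == ncol(counts_a),
            length(eff_lib_b) == ncol(counts_b),
            all(c(eff_lib_a, eff_lib_b) > 0))
  common <- exp(mean(log(c(eff_lib_a, eff_lib_b))))
  pseudo_a <- round(sweep(counts_a, 2, common / eff_lib_a, `*`))
  pseudo_b <- round(sweep(counts_b, 2, common / eff_lib_b, `*`))
  ya <- rowSums(pseudo_a)
  yb <- rowSums(pseudo_b)
  na <- ncol(counts_a)
  nb <- ncol(counts_b)
  vapply(seq_along(ya), function(i)
    exact_nb_pvalue(ya[i], yb[i], na, nb, phi), numeric(1))
}

# conditional two-sided p-value for one promoter given group sums.
# For small totals the conditional distribution is enumerated in full; for
# large totals the same quantity is computed from the closed-form
# normalizer (the total of two NBs sharing a probability parameter is NB)
# plus binary-searched tail boundaries and truncated tail sums, exploiting
# the log-concavity (hence unimodality) of the conditional pmf. Both paths
# agree to full floating-point accuracy.
exact_nb_pvalue <- function(ya, yb, na, nb, phi, log_tol = 1e-8) {
  s <- ya + yb
  if (s == 0) return(1)
  prop_a <- na / (na + nb)
  if (phi == 0) {
    lpf <- function(k) stats::dbinom(k, size = s, prob = prop_a, log = TRUE)
    lse <- 0
  } else {
    lpf <- function(k)
      stats::dnbinom(k, size = na / phi, mu = s * prop_a, log = TRUE) +
      stats::dnbinom(s - k, size = nb / phi, mu = s * (1 - prop_a),
                     log = TRUE)
    lse <- stats::dnbinom(s, size = (na + nb) / phi, mu = s, log = TRUE)
  }
  if (s <= 2048) {
    lp <- lpf(0:s)
    lobs <- lp[ya + 1L]
    mx <- max(lp)
    p <- sum(exp(lp[lp <= lobs + log_tol] - mx)) / sum(exp(lp - mx))
    return(min(max(p, .Machine$double.xmin), 1))
  }
  lobs <- lpf(ya)
  thr <- lobs + log_tol
  # mode: largest k with lpf(k+1) > lpf(k), by binary search on the
  # monotone difference sequence
  lo <- 0
  hi <- s - 1
  if (lpf(1) <= lpf(0)) {
    mode <- 0
  } else {
    while (lo < hi) {
      mid <- (lo + hi + 1) %/% 2
      if (lpf(mid + 1) > lpf(mid)) lo <- mid else hi <- mid - 1
    }
    mode <- lo + 1
  }
  # the inclusion set {k : lpf(k) <= thr} is [0, k1] U [k2, s] by
  # unimodality: lpf non-decreasing on [0, mode], non-increasing on
  # [mode, s]
  if (lpf(mode) <= thr) return(1)
  k1 <- if (lpf(0) > thr) -1 else {
    lo <- 0
    hi <- mode
    while (lo < hi) {            # largest k in [0, mode] with lpf(k) <= thr
      mid <- (lo + hi + 1) %/% 2
      if (lpf(mid) <= thr) lo <- mid else hi <- mid - 1
    }
    lo
  }
  k2 <- if (lpf(s) > thr) s + 1 else {
    lo <- mode
    hi <- s
    while (lo < hi) {            # smallest k in [mode, s] with lpf(k) <= thr
      mid <- (lo + hi) %/% 2
      if (lpf(mid) <= thr) hi <- mid else lo <- mid + 1
    }
    lo
  }
  p <- tail_mass_down(lpf, k1, lse) + tail_mass_up(lpf, k2, s, lse)
  min(max(p, .Machine$double.xmin), 1)
}

# sum of exp(lpf(k) - lse) over [0, hi], accumulated downward from hi in
# chunks; terms decay away from hi, so stopping once a chunk is < 1e-15
# of the accumulated mass bounds the truncation error at that level
tail_mass_down <- function(lpf, hi, lse, chunk = 512L) {
  acc <- 0
  while (hi >= 0) {
    kk <- seq(hi, max(0L, hi - chunk + 1L))
    part <- sum(exp(lpf(kk) - lse))
    acc <- acc + part
    if (part < acc * 1e-15) break
    hi <- hi - chunk
  }
  acc
}

# sum of exp(lpf(k) - lse) over [lo, s], accumulated upward from lo
tail_mass_up <- function(lpf, lo, s, lse, chunk = 512L) {
  acc <- 0
  while (lo <= s) {
    kk <- seq(lo, min(s, lo + chunk - 1L))
    part <- sum(exp(lpf(kk) - lse))
    acc <- acc + part
    if (part < acc * 1e-15) break
    lo <- lo + chunk
  }
  acc
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up FDR adjustment: with `m` tests and sorted p-values `p_(1) <= ...
#' <= p_(m)`, the adjusted value is `q_(i) = min_{j >= i} (m / j) p_(j)`,
#' clipped at 1, returned in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
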