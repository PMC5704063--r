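# Independent brute-force oracles and fixture builders used across the
# suite. Oracles are written from the definitions, not from the package's
# implementation paths.

# median-of-ratios size factors, straight from the definition
oracle_rle <- function(counts) {
  ref <- which(apply(counts > 0, 1, all))
  gm <- apply(counts[ref, , drop = FALSE], 1, function(r) exp(mean(log(r))))
  f <- apply(counts[ref, , drop = FALSE], 2, function(col)
    median(col / gm))
  f / exp(mean(log(f)))
}

# NB pmf from first principles (lgamma), variance = mu + phi mu^2;
# phi = 0 is the Poisson pmf
oracle_nb_lpmf <- function(k, mu, phi) {
  if (phi == 0) return(k * log(mu) - mu - lgamma(k + 1))
  r <- 1 / phi
  lgamma(k + r) - lgamma(r) - lgamma(k + 1) +
    r * log(r / (r + mu)) + k * log(mu / (r + mu))
}

# conditional exact-test p-value by full enumeration of the conditional
# distribution of the group-A sum given the total; same documented tie
# rule (relative log tolerance 1e-8) as the implementation
oracle_exact_p <- function(ya, yb, na, nb, phi, log_tol = 1e-8) {
  s <- ya + yb
  if (s == 0) return(1)
  k <- 0:s
  lp <- oracle_nb_lpmf(k, s * na / (na + nb), phi / na) +
    oracle_nb_lpmf(s - k, s * nb / (na + nb), phi / nb)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  lobs <- lp[ya + 1]
  sum(pr[lp <= lobs + log_tol])
}

# BH step-up from the definition: q_(i) = min_{j>=i} (m/j) p_(j), capped
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m))
    q[ord[i]] <- min(1, min((m / i:m) * p[ord][i:m]))
  q
}

# naive agglomerative clustering on a distance matrix; linkage recomputed
# from the original pairwise distances at every step
oracle_agglomerate <- function(d, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      cross <- d[clusters[[i]], clusters[[j]], drop = FALSE]
      h <- if (linkage == "complete") max(cross) else mean(cross)
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    heights <- c(heights, best_h)
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

# leaf partition (list of sorted leaf-index sets) from a cut, order-free
partition_of <- function(labels_vec) {
  unname(lapply(split(seq_along(labels_vec), labels_vec), sort))
}

same_partition <- function(a, b) {
  key <- function(p) sort(vapply(p, paste, character(1), collapse = ","))
  identical(key(a), key(b))
}

# hypergeometric upper-tail by explicit enumeration with choose()
oracle_hyper_p <- function(q, k_cat, n_univ, k_sel) {
  kk <- q:min(k_cat, k_sel)
  sum(choose(k_cat, kk) * choose(n_univ - k_cat, k_sel - kk)) /
    choose(n_univ, k_sel)
}

# random raw-tag ExpressionMatrix fixture
rand_counts <- function(n = 20, m = 4, lambda = 50, prefix = "p1@G") {
  v <- matrix(rpois(n * m, lambda), n, m,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n)),
                              sprintf("s%02d", seq_len(m))))
  promscreen::expression_matrix(v, "raw_tags")
}

# tpm matrix built directly from given values (bypassing normalization)
tpm_fixture <- function(values, sample_meta = NULL) {
  promscreen::expression_matrix(values, "tpm", sample_meta)
}
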