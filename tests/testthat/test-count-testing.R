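test_that("common dispersion is recovered by pooled method of moments", {
  # hand example: normalized counts (10, 30) -> m 20, s^2 200, phi 0.45;
  # equal column sums keep normalization a no-op
  v <- matrix(c(10, 30, 30, 10), 2, 2, byrow = TRUE,
              dimnames = list(c("pA", "pB"), c("s1", "s2")))
  est <- estimate_common_dispersion(expression_matrix(v, "raw_tags"),
                                    c("g", "g"))
  expect_equal(est$phi, 0.45)
  expect_equal(est$n_promoters_used, 2L)

  # Poisson data: estimate collapses towards zero
  set.seed(41)
  for (i in 1:3) {
    v <- matrix(rpois(1000 * 6, 100), 1000, 6,
                dimnames = list(sprintf("p%04d", 1:1000), paste0("s", 1:6)))
    est <- estimate_common_dispersion(expression_matrix(v, "raw_tags"),
                                      rep(c("a", "b"), each = 3))
    expect_lte(est$phi, 0.02)
  }

  # NB data with phi = 0.2: recovered within a factor-of-two band
  set.seed(42)
  v <- matrix(rnbinom(2000 * 12, size = 5, mu = 200), 2000, 12,
              dimnames = list(sprintf("p%04d", 1:2000), paste0("s", 1:12)))
  est <- estimate_common_dispersion(expression_matrix(v, "raw_tags"),
                                    rep(c("a", "b"), each = 6))
  expect_gte(est$phi, 0.1)
  expect_lte(est$phi, 0.3)

  expect_error(estimate_common_dispersion(
    expression_matrix(v[, 1:2], "raw_tags"), c("a", "b")),
    "explicit dispersion")
})

test_that("exact test matches conditional enumeration and is symmetric", {
  # balanced identical groups sit at the conditional mode: p = 1
  expect_equal(nb_exact_test(c(5, 5), c(5, 5), phi = 0.3,
                             eff_lib_a = c(1, 1), eff_lib_b = c(1, 1)), 1)

  # Poisson case, 1 vs 1, split (0, 10): conditional Binomial(10, 1/2)
  expect_equal(nb_exact_test(0, 10, phi = 0, eff_lib_a = 1, eff_lib_b = 1),
               2 / 1024, tolerance = 1e-12)

  # total zero -> p = 1 by convention
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), phi = 0.1,
                             eff_lib_a = c(1, 1), eff_lib_b = c(1, 1)), 1)

  # symmetry under group exchange
  set.seed(43)
  for (i in 1:25) {
    a <- rpois(3, 40)
    b <- rpois(2, 40)
    phi <- runif(1, 0, 0.5)
    expect_equal(
      nb_exact_test(a, b, phi, eff_lib_a = rep(1, 3), eff_lib_b = rep(1, 2)),
      nb_exact_test(b, a, phi, eff_lib_a = rep(1, 2), eff_lib_b = rep(1, 3)),
      tolerance = 1e-12)
  }

  expect_error(nb_exact_test(c(1, 2), c(1, 2), phi = -0.1), "phi")
  expect_error(nb_exact_test(c(1.5, 2), c(1, 2), phi = 0.1), "integer")
})

test_that("exact test agrees with the installed edgeR small-p exact test", {
  set.seed(44)
  for (i in 1:20) {
    a <- matrix(rnbinom(6, size = 10, mu = 60), 2, 3)
    b <- matrix(rnbinom(6, size = 10, mu = 60), 2, 3)
    phi <- sample(c(0.05, 0.2, 0.5), 1)
    ours <- nb_exact_test(a, b, phi,
                          eff_lib_a = rep(1e6, 3), eff_lib_b = rep(1e6, 3))
    theirs <- edgeR::exactTestBySmallP(a, b, dispersion = phi)
    expect_equal(ours, as.vector(theirs), tolerance = 1e-6)
  }
})

test_that("large-total fast path equals full conditional enumeration", {
  set.seed(45)
  for (i in 1:40) {
    s <- sample(2100:6000, 1)
    ya <- sample(0:s, 1)
    na <- sample(1:4, 1)
    nb <- sample(c(2:5, 120), 1)
    phi <- sample(c(0, 0.05, 0.3), 1)
    got <- promscreen:::exact_nb_pvalue(ya, s - ya, na, nb, phi)
    want <- oracle_exact_p(ya, s - ya, na, nb, phi)
    # floor guards against denormal-range disagreement far below any
    # usable significance level
    expect_equal(max(got, 1e-250), max(want, 1e-250), tolerance = 1e-8)
  }
})

test_that("BH adjustment reproduces the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(46)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("paired differential calls combine exact test and donor fold changes", {
  # hand fold-change example: donor ratios 3, 2, 2.5 with c = 0
  donors <- sprintf("donor_%d", 1:3)
  meta <- data.frame(
    sample_id = c(paste0("a", 1:3), paste0("b", 1:3)),
    group = rep(c("A", "B"), each = 3),
    donor_id = rep(donors, 2))
  tpm_v <- rbind(px = c(10, 10, 10, 30, 20, 25),
                 py = c(50, 50, 50, 50, 50, 50))
  colnames(tpm_v) <- meta$sample_id
  cnt_v <- round(tpm_v)
  tpm <- tpm_fixture(tpm_v, meta)
  cnt <- expression_matrix(cnt_v, "raw_tags", meta)
  rec <- differential_expression(tpm, cnt, paste0("a", 1:3), paste0("b", 1:3),
                                 mode = "paired", pseudocount = 0,
                                 phi = 0.05)
  expect_equal(rec$mean_fc[1], (3 * 2 * 2.5)^(1 / 3), tolerance = 1e-12)
  expect_equal(rec$mean_fc[2], 1)
  expect_equal(rec$call[2], "ns")
  expect_true(all(rec$adj_p >= rec$p))

  # swapping groups inverts fold changes and swaps the calls
  rec_sw <- differential_expression(tpm, cnt, paste0("b", 1:3),
                                    paste0("a", 1:3),
                                    mode = "paired", pseudocount = 0,
                                    phi = 0.05)
  expect_equal(rec_sw$mean_fc, 1 / rec$mean_fc, tolerance = 1e-12)
  expect_equal(rec_sw$p, rec$p, tolerance = 1e-12)
  swap <- c(up = "down", down = "up", ns = "ns")
  expect_equal(unname(swap[rec$call]), rec_sw$call)

  # identical groups: everything ns at fold change 1
  same_v <- tpm_v[, c(1:3, 1:3)]
  colnames(same_v) <- meta$sample_id
  same <- tpm_fixture(same_v, meta)
  same_cnt <- expression_matrix(round(same_v), "raw_tags", meta)
  rec_id <- differential_expression(same, same_cnt, paste0("a", 1:3),
                                    paste0("b", 1:3), mode = "paired",
                                    pseudocount = 0, phi = 0.05)
  expect_true(all(rec_id$mean_fc == 1))
  expect_true(all(rec_id$call == "ns"))

  # unmatched donors abort with the offender named
  bad_meta <- meta
  bad_meta$donor_id[6] <- "donor_9"
  bad_cnt <- expression_matrix(cnt_v, "raw_tags", bad_meta)
  expect_error(differential_expression(tpm, bad_cnt, paste0("a", 1:3),
                                       paste0("b", 1:3), mode = "paired"),
               "donor_9")
})

test_that("planted fold changes are recovered in a paired design", {
  set.seed(47)
  hits <- 0
  for (seed in 1:5) {
    cfg <- diff_sim_config(n_promoters = 600, n_up = 15, n_down = 15,
                           seed = seed)
    sim <- simulate_differentiation(cfg)
    sf <- rle_size_factors(sim$matrix)
    tpm <- to_tpm(sim$matrix, sf)
    meta <- sim$matrix$sample_meta
    rec <- differential_expression(
      tpm, sim$matrix,
      meta$sample_id[meta$group == "progenitor"],
      meta$sample_id[meta$group == "differentiated"],
      mode = "paired", size_factors = sf)
    res <- evaluate_recovery(c(sim$truth$planted_up, sim$truth$planted_down),
                             rec$peak_id[rec$call != "ns"])
    hits <- hits + (res$sensitivity >= 0.8)
  }
  expect_gte(hits, 4)
})
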