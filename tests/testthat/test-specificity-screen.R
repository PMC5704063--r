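# small helper: a tpm matrix with explicit target/reference structure
screen_fixture <- function(target_rows, ref_rows) {
  stopifnot(nrow(target_rows) == nrow(ref_rows))
  v <- cbind(target_rows, ref_rows)
  colnames(v) <- c(paste0("t", seq_len(ncol(target_rows))),
                   paste0("r", seq_len(ncol(ref_rows))))
  tpm_fixture(v)
}

test_that("the five criteria are evaluated with strict inequalities", {
  # fold-change criterion fails: log2(20.1 / 1.1) ~ 4.19 < 5
  tv <- matrix(c(15, 20, 25), 1)
  rv <- matrix(c(5, 0, 0, 0, 0), 1)                      # mean 1, max 5
  rownames(tv) <- rownames(rv) <- "pA"
  m <- screen_fixture(tv, rv)
  th <- screen_thresholds(fc_pseudocount = 0.1)
  rec <- specificity_screen(m, paste0("t", 1:3), paste0("r", 1:5),
                            c(pA = 1e-9), th)
  expect_true(rec$crit1 && rec$crit2 && rec$crit3 && rec$crit5)
  expect_false(rec$crit4)
  expect_equal(rec$log2_fc, log2(20.1 / 1.1))
  expect_false(rec$specific)

  # strong marker: all five pass (log2(200.1/0.1) ~ 11)
  tv <- matrix(c(200, 210, 190), 1, dimnames = list("pB", NULL))
  rv <- matrix(0, 1, 5, dimnames = list("pB", NULL))
  rec <- specificity_screen(screen_fixture(tv, rv), paste0("t", 1:3),
                            paste0("r", 1:5), c(pB = 1e-6), th)
  expect_true(rec$specific)
  expect_true(all(unlist(rec[paste0("crit", 1:5)])))

  # silent in target: criterion 1 fails regardless of the reference
  tv <- matrix(0, 1, 3, dimnames = list("pC", NULL))
  rv <- matrix(0, 1, 5, dimnames = list("pC", NULL))
  rec <- specificity_screen(screen_fixture(tv, rv), paste0("t", 1:3),
                            paste0("r", 1:5), c(pC = 1e-6), th)
  expect_false(rec$crit1)
  expect_false(rec$specific)

  # boundary values fail (strict inequalities)
  tv <- matrix(10, 1, 3, dimnames = list("pD", NULL))    # min == 10
  rv <- matrix(3, 1, 5, dimnames = list("pD", NULL))     # mean == 3
  rec <- specificity_screen(screen_fixture(tv, rv), paste0("t", 1:3),
                            paste0("r", 1:5), c(pD = 1e-6), th)
  expect_false(rec$crit1)
  expect_false(rec$crit2)

  # input validation
  m <- screen_fixture(matrix(1, 1, 2, dimnames = list("pE", NULL)),
                      matrix(1, 1, 2, dimnames = list("pE", NULL)))
  expect_error(specificity_screen(m, c("t1", "t2"), c("t2", "r1"),
                                  c(pE = 0.5), th), "overlap")
  expect_error(specificity_screen(m, c("t1", "t2"), c("r1", "r2"),
                                  c(other = 0.5), th), "missing promoter")
})

test_that("designed violators flip exactly one criterion", {
  th <- screen_thresholds(fc_pseudocount = 0.1)
  base_t <- c(200, 210, 190)
  base_r <- rep(0, 6)
  cases <- list(
    crit1 = list(t = c(9, 210, 190), r = base_r),       # one target at 9 tpm
    crit2 = list(t = base_t * 50, r = rep(3.5, 6)),     # ref mean 3.5
    crit5 = list(t = base_t, r = base_r, p = 0.5))      # weak significance
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    tv <- matrix(cs$t, 1, dimnames = list("pX", NULL))
    rv <- matrix(cs$r, 1, dimnames = list("pX", NULL))
    p <- c(pX = if (is.null(cs$p)) 1e-9 else cs$p)
    rec <- specificity_screen(screen_fixture(tv, rv), paste0("t", 1:3),
                              paste0("r", 1:6), p, th)
    flags <- unlist(rec[paste0("crit", 1:5)])
    expect_equal(sum(!flags), 1L, info = nm)
    expect_false(flags[nm])
  }
  # crit3 violator: one reference sample above the target mean but tiny
  # reference mean and huge fold change
  tv <- matrix(c(150, 160, 170), 1, dimnames = list("pX", NULL))
  rv <- matrix(c(170, rep(0, 99)), 1, dimnames = list("pX", NULL))
  rec <- specificity_screen(screen_fixture(tv, rv), paste0("t", 1:3),
                            paste0("r", 1:100), c(pX = 1e-9), th)
  flags <- unlist(rec[paste0("crit", 1:5)])
  expect_equal(which(!flags), c(crit3 = 3L))
})

test_that("screen results are order-invariant and threshold-monotone", {
  set.seed(51)
  n <- 120
  tv <- matrix(rlnorm(n * 3, log(8), 2), n)
  rv <- matrix(rlnorm(n * 40, log(1), 2), n, 40)
  rownames(tv) <- rownames(rv) <- sprintf("p%03d", seq_len(n))
  m <- screen_fixture(tv, rv)
  p <- setNames(runif(n)^3, rownames(tv))
  th <- screen_thresholds()
  rec <- specificity_screen(m, paste0("t", 1:3), paste0("r", 1:40), p, th)

  # permuting promoter rows and reference order changes nothing
  perm <- sample(n)
  m2 <- tpm_fixture(m$values[perm, c(paste0("t", 1:3),
                                     sample(paste0("r", 1:40)))])
  rec2 <- specificity_screen(m2, paste0("t", 1:3), paste0("r", 1:40), p, th)
  expect_equal(rec2$specific[match(rec$peak_id, rec2$peak_id)], rec$specific)

  # tightening any single threshold never enlarges the specific set
  tighter <- list(
    screen_thresholds(min_target_tpm = 20),
    screen_thresholds(max_ref_mean_tpm = 1),
    screen_thresholds(min_log2fc = 7),
    screen_thresholds(alpha = 0.001))
  for (th2 in tighter) {
    rec2 <- specificity_screen(m, paste0("t", 1:3), paste0("r", 1:40), p, th2)
    expect_true(all(rec$peak_id[rec2$specific] %in% rec$peak_id[rec$specific]))
  }
})

test_that("screen intersection is a plain set intersection", {
  mk <- function(ids, specific) data.frame(peak_id = ids,
                                           specific = ids %in% specific)
  a <- mk(c("x", "y", "z", "w"), c("x", "y", "z"))
  b <- mk(c("x", "y", "z", "w"), c("y", "z", "w"))
  expect_setequal(intersect_screens(a, b), c("y", "z"))
  expect_length(intersect_screens(mk("x", "x"), mk("y", "y")), 0)

  set.seed(52)
  for (i in 1:20) {
    ids <- sprintf("p%02d", 1:30)
    a <- mk(ids, sample(ids, 10))
    b <- mk(ids, sample(ids, 10))
    common <- intersect_screens(a, b)
    expect_true(all(common %in% a$peak_id[a$specific]))
    expect_true(all(common %in% b$peak_id[b$specific]))
  }
})

test_that("gene-locus collapsing matches the published table shape", {
  rec <- parse_promoter_id(c("p1@A", "p2@A", "p3@B"))
  loci <- collapse_to_loci(c("p1@A", "p2@A", "p3@B"), rec)
  expect_length(loci, 2)
  expect_equal(loci$A, c("p1@A", "p2@A"))
  expect_equal(loci$B, "p3@B")

  # all singletons: one locus per promoter
  ids <- sprintf("p1@G%d", 1:7)
  expect_length(collapse_to_loci(ids, parse_promoter_id(ids)), 7)

  # the published 45-promoter / 28-locus marker table collapses exactly;
  # location-style peaks are tied to their locus by the table's gene column
  tab <- read.delim(system.file("extdata", "cec_specific_promoters.tsv",
                                package = "promscreen"))
  expect_equal(nrow(tab), 45L)
  rec <- parse_promoter_id(tab$peak_id)
  rec$gene_symbol <- tab$gene_symbol
  loci <- collapse_to_loci(tab$peak_id, rec)
  expect_length(loci, 28)
  expect_equal(sum(lengths(loci)), 45L)
  expect_equal(loci$PITX2, c("p1@PITX2", "p2@PITX2", "p3@PITX2", "p8@PITX2"))
})

test_that("gene specificity is classified by the fate of the main promoter", {
  ids <- c("p1@TFAP2B", "p2@TFAP2B", "p3@TFAP2B", "p9@TFAP2B",
           "p1@ERG", "p5@ERG",
           "p1@POU6F2", "p3@POU6F2")
  rec <- parse_promoter_id(ids)
  ref <- paste0("r", 1:4)
  tgt <- paste0("t", 1:2)
  v <- rbind(c(300, 300, 0, 0, 0, 0),       # p1@TFAP2B specific
             c(200, 200, 0, 0, 0, 0),
             c(100, 100, 0, 0, 0, 0),
             c(50, 50, 0, 0, 0, 0),
             c(80, 90, 500, 450, 300, 200), # p1@ERG broadly expressed
             c(120, 110, 0, 0, 0, 0),       # p5@ERG specific
             c(0, 0, 0, 0, 0, 0),           # p1@POU6F2 silent everywhere
             c(150, 140, 0, 1.77, 0, 0))    # p3@POU6F2 specific
  dimnames(v) <- list(ids, c(tgt, ref))
  tpm <- tpm_fixture(v)
  screen <- data.frame(
    peak_id = ids,
    specific = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))

  tfap2b <- classify_gene_specificity("TFAP2B", screen, tpm, rec, ref)
  expect_equal(tfap2b$category, "major_promoter_specific")
  expect_setequal(tfap2b$specific_promoters,
                  c("p1@TFAP2B", "p2@TFAP2B", "p3@TFAP2B"))

  erg <- classify_gene_specificity("ERG", screen, tpm, rec, ref)
  expect_equal(erg$category, "alternative_promoter_only")
  expect_equal(erg$p1_ref_max, 500)

  # main promoter not specific but silent in the reference: still a
  # major-promoter-specific locus
  pou <- classify_gene_specificity("POU6F2", screen, tpm, rec, ref)
  expect_equal(pou$category, "major_promoter_specific")

  expect_error(classify_gene_specificity("NOGENE", screen, tpm, rec, ref),
               "no specific promoter")
})

test_that("overlap with differential calls reports directional fractions", {
  ids <- sprintf("p%02d", 1:45)
  diff <- data.frame(peak_id = ids,
                     call = c(rep("up", 25), rep("down", 2), rep("ns", 18)))
  ov <- overlap_with_differential(ids, diff)
  expect_equal(ov$n_up, 25)
  expect_equal(ov$n_down, 2)
  expect_equal(ov$n_total, 45)
  expect_equal(ov$frac_up, 25 / 45, tolerance = 1e-12)

  # no calls at all
  none <- data.frame(peak_id = ids, call = rep("ns", 45))
  ov0 <- overlap_with_differential(ids, none)
  expect_equal(c(ov0$n_up, ov0$n_down, ov0$frac_up), c(0, 0, 0))

  # peaks missing from the records count as ns, with a warning
  expect_warning(ov2 <- overlap_with_differential(c(ids, "p99"), diff),
                 "missing")
  expect_equal(ov2$n_total, 46)
  expect_true(ov2$n_up + ov2$n_down <= ov2$n_total)

  expect_error(overlap_with_differential(character(0), diff), "empty")
})

test_that("over-representation test matches hypergeometric enumeration", {
  univ <- paste0("g", 1:20)
  res <- enrichment_test(paste0("g", 1:5), list(hit = paste0("g", 1:5)),
                         univ)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)

  # a category equal to the universe can never be enriched
  res <- enrichment_test(paste0("g", 1:5), list(all = univ), univ)
  expect_equal(res$p, 1)

  expect_error(enrichment_test("nope", list(a = univ), univ), "universe")

  set.seed(53)
  for (i in 1:30) {
    n <- sample(10:30, 1)
    univ <- paste0("g", seq_len(n))
    sel <- sample(univ, sample(2:8, 1))
    cat1 <- sample(univ, sample(2:10, 1))
    res <- enrichment_test(sel, list(c1 = cat1), univ)
    q <- length(intersect(sel, cat1))
    expect_equal(res$p, oracle_hyper_p(q, length(cat1), n, length(sel)),
                 tolerance = 1e-12)
  }
})
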