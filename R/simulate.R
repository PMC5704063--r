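#' Configuration for the synthetic target-vs-atlas design
#'
#' Emulates a CAGE screen of a small target group (biological triplicates
#' of one cell type) against a large reference atlas of heterogeneous
#' tissue or primary-cell samples. Counts are negative binomial with
#' `variance = mu + phi * mu^2`; per-promoter baselines are log-normal
#' (median 10 tpm, heavy-tailed), library sizes are log-normal around 1e6
#' tags, and reference samples get per-sample log-normal baseline jitter so
#' that the screen's max-vs-mean criterion is non-trivially exercised.
#' Planted specific promoters keep their drawn baseline times
#' `planted_effect` in the target samples but are nearly silent
#' (`planted_ref_tpm`) in the reference - the expression pattern of a
#' genuine cell-type-restricted promoter.
#'
#' @param n_promoters total number of promoters.
#' @param promoters_per_gene integer vector of allowed promoters-per-locus
#'   counts, sampled uniformly per gene.
#' @param n_target,n_reference sample counts (defaults 3 and 180).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline activity
#'   parameters (tpm units; defaults log(10) and 1.5).
#' @param phi NB dispersion (default 0.1).
#' @param lib_meanlog,lib_sdlog log-normal library-size parameters
#'   (defaults log(1e6) and 0.25).
#' @param ref_jitter_sdlog per-reference-sample baseline jitter (default
#'   0.5).
#' @param n_planted number of planted specific promoters (default 30).
#' @param planted_effect target-mean multiplier for planted promoters
#'   (default 64 = 2^6).
#' @param planted_ref_tpm near-zero reference baseline of planted
#'   promoters (default 0.05 tpm).
#' @param seed integer seed; every simulation is deterministic given it.
#' @return list of class `atlas_sim_config`.
#' @export
atlas_sim_config <- function(n_promoters = 10000,
                             promoters_per_gene = 1:8,
                             n_target = 3, n_reference = 180,
                             baseline_meanlog = log(10),
                             baseline_sdlog = 1.5,
                             phi = 0.1,
                             lib_meanlog = log(1e6), lib_sdlog = 0.25,
                             ref_jitter_sdlog = 0.5,
                             n_planted = 30, planted_effect = 64,
                             planted_ref_tpm = 0.05,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_promoters >= 1, cfg$n_target >= 1, cfg$n_reference >= 1,
            cfg$phi >= 0, cfg$planted_effect >= 1,
            cfg$n_planted <= cfg$n_promoters, cfg$planted_ref_tpm >= 0)
  structure(cfg, class = "atlas_sim_config")
}

#' Draw the gene structure and planted set of an atlas simulation
#'
#' Separates the truth (gene/promoter layout, baselines, planted specific
#' promoters) from the count draws so that several simulated facets can
#' share it.
#'
#' @param config an [atlas_sim_config()]; its seed governs the draw.
#' @param reseed set the RNG from `config$seed` first (default `TRUE`).
#' @return list with `genes` (data.frame `peak_id`, `gene_symbol`, `rank`,
#'   `baseline`) and `planted` (row indices of planted specific promoters).
#' @export
atlas_structure <- function(config, reseed = TRUE) {
  stopifnot(inherits(config, "atlas_sim_config"))
  if (reseed) set.seed(config$seed)
  genes <- simulate_gene_structure(config$n_promoters,
                                   config$promoters_per_gene,
                                   config$baseline_meanlog,
                                   config$baseline_sdlog)
  list(genes = genes,
       planted = sort(sample(config$n_promoters, config$n_planted)))
}

# gene/promoter naming shared by both designs: genes G0001..; peaks
# p<rank>@G<gene> with rank by descending baseline within the gene
simulate_gene_structure <- function(n_promoters, promoters_per_gene,
                                    baseline_meanlog, baseline_sdlog) {
  sizes <- integer(0)
  while (sum(sizes) < n_promoters)
    sizes <- c(sizes, sample(promoters_per_gene, 64, replace = TRUE))
  sizes <- sizes[cumsum(sizes) - sizes < n_promoters]
  sizes[length(sizes)] <- n_promoters - sum(sizes[-length(sizes)])
  gene <- rep(sprintf("G%05d", seq_along(sizes)), sizes)
  baseline <- stats::rlnorm(n_promoters, baseline_meanlog, baseline_sdlog)
  rank <- as.integer(stats::ave(baseline, gene, FUN = function(b)
    match(seq_along(b), order(-b))))
  data.frame(peak_id = sprintf("p%d@%s", rank, gene),
             gene_symbol = gene, rank = rank, baseline = baseline,
             stringsAsFactors = FALSE)
}

#' Simulate a target-vs-atlas CAGE count dataset with planted truth
#'
#' @param config an [atlas_sim_config()].
#' @param structure optional pre-drawn gene structure and planted set from
#'   [atlas_structure()], letting several facets (different sample layouts)
#'   share one planted truth.
#' @return list with `matrix` (an [expression_matrix()] of raw tags, target
#'   samples grouped as `"target"`, atlas samples as `"reference"`),
#'   `truth` (list: `planted_specific` peak IDs, `expected_target_mean`
#'   expected per-sample target counts at 1e6 tags, `gene_map`, `config`).
#' @export
simulate_atlas <- function(config, structure = NULL) {
  stopifnot(inherits(config, "atlas_sim_config"))
  set.seed(config$seed)
  if (is.null(structure)) structure <- atlas_structure(config, reseed = FALSE)
  genes <- structure$genes
  n_p <- config$n_promoters
  if (nrow(genes) != n_p)
    stop("structure does not match config$n_promoters")
  planted <- structure$planted
  base_target <- genes$baseline
  base_ref <- genes$baseline
  if (config$planted_effect > 1) {
    base_target[planted] <- genes$baseline[planted] * config$planted_effect
    base_ref[planted] <- config$planted_ref_tpm
  }
  # planted_effect == 1 disables the perturbation entirely: the planted
  # set becomes a pure-null decoy labeling for false-positive checks

  n_t <- config$n_target
  n_r <- config$n_reference
  libs <- stats::rlnorm(n_t + n_r, config$lib_meanlog, config$lib_sdlog)
  mu <- matrix(0, n_p, n_t + n_r)
  for (j in seq_len(n_t))
    mu[, j] <- base_target * libs[j] / 1e6
  for (j in seq_len(n_r)) {
    jitter <- stats::rlnorm(n_p, 0, config$ref_jitter_sdlog)
    mu[, n_t + j] <- base_ref * jitter * libs[n_t + j] / 1e6
  }
  counts <- rnbinom_mat(mu, config$phi)
  sample_ids <- c(sprintf("target_%d", seq_len(n_t)),
                  sprintf("ref_%03d", seq_len(n_r)))
  dimnames(counts) <- list(genes$peak_id, sample_ids)
  meta <- data.frame(
    sample_id = sample_ids,
    group = rep(c("target", "reference"), c(n_t, n_r)),
    facet = "unspecified",
    donor_id = NA_character_,
    replicate_id = c(sprintf("rep%d", seq_len(n_t)), rep(NA, n_r)),
    stringsAsFactors = FALSE)
  list(matrix = expression_matrix(counts, "raw_tags", meta),
       truth = list(planted_specific = genes$peak_id[planted],
                    expected_target_mean = base_target,
                    gene_map = genes[c("peak_id", "gene_symbol", "rank")],
                    config = config))
}

rnbinom_mat <- function(mu, phi) {
  counts <- if (phi == 0) stats::rpois(length(mu), mu) else
    stats::rnbinom(length(mu), size = 1 / phi, mu = mu)
  matrix(counts, nrow = nrow(mu))
}

#' Configuration for the paired progenitor-vs-differentiated design
#'
#' Emulates donor-matched pairs of samples in two states (progenitors and
#' their in vitro differentiated derivatives). Each donor carries a shared
#' log-normal per-promoter effect, inducing the within-donor correlation of
#' a paired design; planted promoters are multiplied (up) or divided
#' (down) by `effect` in the differentiated state of every donor.
#'
#' @param n_promoters total number of promoters (default 5000).
#' @param n_donors number of donor pairs (default 3).
#' @param promoters_per_gene as in [atlas_sim_config()].
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters
#'   (defaults log(200) tpm and 1.2: the designs compared here profile
#'   promoters active in the cell type, so baselines sit well above the
#'   detection floor).
#' @param phi NB dispersion (default 0.05).
#' @param lib_meanlog,lib_sdlog library-size distribution (defaults
#'   log(1e6), 0.25).
#' @param donor_sdlog per-donor shared log-normal effect (default 0.15,
#'   i.e. ~15% between-donor CV for matched cultures; sized so the
#'   unpaired exact test's effective dispersion stays near the generating
#'   `phi`).
#' @param n_up,n_down planted promoter counts (defaults 100 each).
#' @param effect planted fold change (default 4).
#' @param seed integer seed.
#' @return list of class `diff_sim_config`.
#' @export
diff_sim_config <- function(n_promoters = 5000, n_donors = 3,
                            promoters_per_gene = 1:8,
                            baseline_meanlog = log(200),
                            baseline_sdlog = 1.2,
                            phi = 0.05,
                            lib_meanlog = log(1e6), lib_sdlog = 0.25,
                            donor_sdlog = 0.15,
                            n_up = 100, n_down = 100, effect = 4,
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_promoters >= 1, cfg$n_donors >= 2, cfg$phi >= 0,
            cfg$effect > 1, cfg$n_up + cfg$n_down <= cfg$n_promoters)
  structure(cfg, class = "diff_sim_config")
}

#' Simulate a paired two-state differentiation count dataset
#'
#' @param config a [diff_sim_config()].
#' @return list with `matrix` (an [expression_matrix()] of raw tags;
#'   samples `prog_<d>` / `diff_<d>` with donor-paired metadata, `group`
#'   set to `"progenitor"` / `"differentiated"`) and `truth` (list:
#'   `planted_up`, `planted_down`, `gene_map`, `config`).
#' @export
simulate_differentiation <- function(config) {
  stopifnot(inherits(config, "diff_sim_config"))
  set.seed(config$seed)
  genes <- simulate_gene_structure(config$n_promoters,
                                   config$promoters_per_gene,
                                   config$baseline_meanlog,
                                   config$baseline_sdlog)
  n_p <- config$n_promoters
  planted <- sample(n_p, config$n_up + config$n_down)
  up <- sort(planted[seq_len(config$n_up)])
  down <- sort(planted[config$n_up + seq_len(config$n_down)])
  fold <- rep(1, n_p)
  fold[up] <- config$effect
  fold[down] <- 1 / config$effect

  n_d <- config$n_donors
  libs <- stats::rlnorm(2 * n_d, config$lib_meanlog, config$lib_sdlog)
  mu <- matrix(0, n_p, 2 * n_d)
  for (d in seq_len(n_d)) {
    donor_eff <- stats::rlnorm(n_p, 0, config$donor_sdlog)
    mu[, d] <- genes$baseline * donor_eff * libs[d] / 1e6
    mu[, n_d + d] <- genes$baseline * donor_eff * fold * libs[n_d + d] / 1e6
  }
  counts <- rnbinom_mat(mu, config$phi)
  sample_ids <- c(sprintf("prog_%d", seq_len(n_d)),
                  sprintf("diff_%d", seq_len(n_d)))
  dimnames(counts) <- list(genes$peak_id, sample_ids)
  meta <- data.frame(
    sample_id = sample_ids,
    group = rep(c("progenitor", "differentiated"), each = n_d),
    facet = "unspecified",
    donor_id = rep(sprintf("donor_%d", seq_len(n_d)), 2),
    replicate_id = NA_character_,
    stringsAsFactors = FALSE)
  list(matrix = expression_matrix(counts, "raw_tags", meta),
       truth = list(planted_up = genes$peak_id[up],
                    planted_down = genes$peak_id[down],
                    gene_map = genes[c("peak_id", "gene_symbol", "rank")],
                    config = config))
}

#' Sensitivity / precision / FDR of a predicted set against planted truth
#'
#' @param truth character vector of planted peak IDs.
#' @param predicted character vector of predicted peak IDs.
#' @return list `sensitivity`, `precision`, `fdr`, `tp`, `fp`, `fn`.
#'   Ratios with zero denominators are `NaN` (flagged undefined), never
#'   errors.
#' @export
evaluate_recovery <- function(truth, predicted) {
  truth <- unique(truth)
  predicted <- unique(predicted)
  tp <- length(intersect(truth, predicted))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  list(sensitivity = if (length(truth)) tp / length(truth) else NaN,
       precision = if (length(predicted)) tp / length(predicted) else NaN,
       fdr = if (length(predicted)) fp / length(predicted) else NaN,
       tp = tp, fp = fp, fn = fn)
}
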