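#' Configuration of a pipeline run
#'
#' Exactly one input source must be given: real-data tables (`expr_path` +
#' `meta_path`) or a simulation config (`simulation`). All thresholds
#' default to the screen's published constants.
#'
#' @param expr_path,meta_path paths to a FANTOM5-style expression table and
#'   its sample metadata (see [read_expression_table()]).
#' @param simulation an [atlas_sim_config()] (screen runs) or a
#'   [diff_sim_config()] (differentiation runs).
#' @param lane_map_path optional TSV (`lane_id`, `sample_id`) of technical
#'   replicates to merge first.
#' @param exclude_samples sample IDs dropped before any analysis (e.g. a
#'   reference sample suspected to contain the target cell type).
#' @param thresholds a [screen_thresholds()] object.
#' @param qc_threshold minimum median within-group Spearman rho (see
#'   [replicate_concordance()]).
#' @param min_reads optional low-count prefilter (see
#'   [low_count_filter()]); `NULL` disables it.
#' @param de_fc_threshold,de_alpha,de_pseudocount differential-call
#'   parameters (see [differential_expression()]).
#' @param facet2_n_target,facet2_n_reference sample layout of the second
#'   screen facet when simulating (the first facet uses the simulation
#'   config as given; the second emulates the primary-cell comparison,
#'   default 2 target vs the same reference count).
#' @param state_a,state_b `group` labels of the two states of a
#'   differentiation run (state_a is the baseline/denominator).
#' @param specific_set character vector of specific peak IDs - or path to
#'   a one-column/TSV file with a `peak_id` column - overlapped with the
#'   differential calls; `NULL` skips the overlap.
#' @param categories named list of gene sets (or path to a YAML file of
#'   `category: [genes]`) for [enrichment_test()]; `NULL` skips it.
#' @param n_clusters clusters cut from the report dendrogram (default 3).
#' @param seed integer seed for every stochastic step.
#' @param out_dir output directory for tables and the manifest; `NULL`
#'   returns results without writing.
#' @return list of class `run_config`.
#' @export
run_config <- function(expr_path = NULL, meta_path = NULL, simulation = NULL,
                       lane_map_path = NULL,
                       exclude_samples = character(0),
                       thresholds = screen_thresholds(),
                       qc_threshold = 0.7, min_reads = NULL,
                       de_fc_threshold = 2, de_alpha = 0.01,
                       de_pseudocount = 1,
                       facet2_n_target = 2, facet2_n_reference = NULL,
                       state_a = "progenitor", state_b = "differentiated",
                       specific_set = NULL, categories = NULL,
                       n_clusters = 3, seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  has_real <- !is.null(expr_path)
  has_sim <- !is.null(simulation)
  if (has_real == has_sim)
    stop("exactly one of expr_path or simulation must be provided")
  if (has_real && is.null(meta_path))
    stop("real-data runs need meta_path alongside expr_path")
  structure(cfg, class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

log_stage <- function(...) message("[promscreen] ", sprintf(...))

drop_excluded <- function(mat, exclude) {
  if (!length(exclude)) return(mat)
  keep <- setdiff(colnames(mat$values), exclude)
  log_stage("exclusion: %d -> %d samples", ncol(mat$values), length(keep))
  mat[, keep]
}

# QC on the target replicates; returns matrix with failing targets dropped
apply_target_qc <- function(counts, tpm, qc_threshold) {
  targets <- counts$sample_meta$sample_id[counts$sample_meta$group == "target"]
  if (length(targets) < 2L) return(list(counts = counts, tpm = tpm, qc = NULL))
  groups <- stats::setNames(rep("target_replicates", length(targets)), targets)
  qc <- replicate_concordance(tpm, groups, threshold = qc_threshold)
  failing <- qc$samples$sample_id[!qc$samples$pass]
  if (length(failing)) {
    log_stage("qc: dropping %s (median rho below %.2f)",
              paste(failing, collapse = ", "), qc_threshold)
    keep <- setdiff(colnames(counts$values), failing)
    counts <- counts[, keep]
    tpm <- tpm[, keep]
  } else {
    log_stage("qc: all %d target replicates concordant", length(targets))
  }
  list(counts = counts, tpm = tpm, qc = qc)
}

screen_one_facet <- function(counts, thresholds, qc_threshold = 0.7) {
  meta <- counts$sample_meta
  target <- meta$sample_id[meta$group == "target"]
  reference <- meta$sample_id[meta$group == "reference"]
  if (!length(target) || !length(reference))
    stop("facet needs both target and reference samples")
  sf <- rle_size_factors(counts)
  tpm <- to_tpm(counts, sf)
  qcd <- apply_target_qc(counts, tpm, qc_threshold = qc_threshold)
  counts <- qcd$counts
  tpm <- qcd$tpm
  target <- intersect(target, colnames(counts$values))
  grp <- ifelse(counts$sample_meta$group == "target", "target", "reference")
  phi <- estimate_common_dispersion(counts, grp, sf)$phi
  eff <- test_scaling_factors(counts, sf)
  names(eff) <- colnames(counts$values)
  p <- nb_exact_test(counts$values[, target, drop = FALSE],
                     counts$values[, reference, drop = FALSE],
                     phi = phi,
                     eff_lib_a = eff[target], eff_lib_b = eff[reference])
  names(p) <- rownames(counts$values)
  rec <- specificity_screen(tpm, target, reference, p, thresholds)
  log_stage("screen: %d/%d promoters specific (phi = %.3f)",
            sum(rec$specific), nrow(rec), phi)
  list(records = rec, tpm = tpm, counts = counts, phi = phi,
       size_factors = sf, qc = qcd$qc,
       target = target, reference = reference)
}

#' Run the end-to-end specificity screen pipeline
#'
#' Orchestrates the full workflow: input (or simulation of two facets
#' sharing one planted truth) -> optional technical-replicate merging ->
#' sample exclusion -> optional low-count filter -> RLE size factors ->
#' tpm -> replicate QC (failing targets dropped) -> per-facet
#' five-criterion screen -> facet intersection -> gene-locus collapsing ->
#' major/alternative-promoter classification -> promoter clustering ->
#' table export with a run manifest.
#'
#' @param config a [run_config()] with either real-data paths (the
#'   metadata's `facet` column splits the reference into facets) or an
#'   [atlas_sim_config()].
#' @return (invisibly) a result bundle: per-facet screen results,
#'   `intersection` peak set, `loci`, `gene_calls`, `cluster_labels`,
#'   `promoter_records`, `truth` (simulation only), `manifest`.
#' @export
run_screen_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)

  facets <- run_stage("input", {
    if (!is.null(config$simulation)) {
      sim_cfg <- config$simulation
      stopifnot(inherits(sim_cfg, "atlas_sim_config"))
      structure_ <- atlas_structure(sim_cfg)
      cfg1 <- sim_cfg
      cfg1$seed <- sim_cfg$seed + 1L
      cfg2 <- sim_cfg
      cfg2$n_target <- config$facet2_n_target
      if (!is.null(config$facet2_n_reference))
        cfg2$n_reference <- config$facet2_n_reference
      cfg2$seed <- sim_cfg$seed + 2L
      sims <- list(tissue = simulate_atlas(cfg1, structure_),
                   primary_cell = simulate_atlas(cfg2, structure_))
      lapply(sims, function(s) s$matrix)
    } else {
      mat <- read_expression_table(config$expr_path, config$meta_path)
      if (!is.null(config$lane_map_path))
        mat <- merge_technical_replicates(
          mat, utils::read.delim(config$lane_map_path,
                                 colClasses = "character"))
      split_facets(mat)
    }
  })
  truth <- if (!is.null(config$simulation)) {
    structure_ <- atlas_structure(config$simulation)
    list(planted_specific = structure_$genes$peak_id[structure_$planted],
         gene_map = structure_$genes[c("peak_id", "gene_symbol", "rank")])
  }

  facets <- run_stage("exclusion", lapply(facets, drop_excluded,
                                          exclude = config$exclude_samples))
  if (!is.null(config$min_reads))
    facets <- run_stage("low_count_filter", lapply(facets, function(m) {
      out <- low_count_filter(m, config$min_reads)
      log_stage("low_count_filter: %d -> %d promoters",
                nrow(m$values), nrow(out$values))
      out
    }))

  results <- run_stage("screen", lapply(facets, screen_one_facet,
                                        thresholds = config$thresholds,
                                        qc_threshold = config$qc_threshold))
  common <- run_stage("intersect",
                      intersect_screens(results[[1]]$records,
                                        results[[2]]$records))
  log_stage("intersection: %d promoters specific in both facets",
            length(common))

  promoter_records <- run_stage("ranks", {
    gene_map <- if (!is.null(truth)) truth$gene_map else {
      parsed <- parse_promoter_id(rownames(facets[[1]]$values))
      parsed[c("peak_id", "gene_symbol")]
    }
    assign_promoter_ranks(facets[[1]], gene_map)
  })
  loci <- run_stage("collapse", collapse_to_loci(common, promoter_records))
  log_stage("collapse: %d promoters over %d gene loci",
            length(common), length(loci))

  gene_calls <- run_stage("classify", {
    genes <- promoter_records$gene_symbol[
      match(names(loci), promoter_records$gene_symbol)]
    genes <- genes[!is.na(genes)]
    calls <- lapply(genes, function(g) tryCatch(
      classify_gene_specificity(g, results[[1]]$records, results[[1]]$tpm,
                                promoter_records,
                                results[[1]]$reference),
      error = function(e) NULL))
    calls[!vapply(calls, is.null, logical(1))]
  })

  cluster_labels <- run_stage("cluster", {
    if (length(common) >= 2L) {
      dend <- hierarchical_cluster(
        results[[1]]$tpm$values[common, , drop = FALSE],
        axis = "rows", distance = "euclidean_log2", linkage = "complete")
      cut_clusters(dend, min(config$n_clusters, length(common)))
    }
  })

  manifest <- screen_manifest(config, results, common, loci, gene_calls)
  if (!is.null(config$out_dir))
    run_stage("export", with_clean_outputs(config$out_dir, {
      for (f in names(results)) {
        export_report(screen_records = results[[f]]$records,
                      cluster_labels = cluster_labels,
                      tpm_matrix = results[[f]]$tpm,
                      dir = file.path(config$out_dir, f),
                      thresholds = config$thresholds)
        write_results_table(results[[f]]$records,
                            file.path(config$out_dir, f, "screen_records.tsv"))
      }
      writeLines(common, file.path(config$out_dir, "intersection_peaks.txt"))
      write_results_table(promoter_records,
                          file.path(config$out_dir, "promoter_records.tsv"))
      writeLines(manifest, file.path(config$out_dir, "manifest.txt"))
    }))

  invisible(list(facets = results, intersection = common, loci = loci,
                 gene_calls = gene_calls, cluster_labels = cluster_labels,
                 promoter_records = promoter_records, truth = truth,
                 manifest = manifest))
}

# split a real-data matrix into per-facet target+reference matrices
split_facets <- function(mat) {
  meta <- mat$sample_meta
  facet_names <- setdiff(unique(meta$facet[meta$group == "reference"]),
                         "unspecified")
  if (!length(facet_names)) facet_names <- "all"
  out <- lapply(facet_names, function(f) {
    ref <- meta$sample_id[meta$group == "reference" &
                            (meta$facet == f | f == "all")]
    tgt <- meta$sample_id[meta$group == "target" &
                            (meta$facet %in% c(f, "unspecified") |
                               f == "all")]
    mat[, c(tgt, ref)]
  })
  names(out) <- facet_names
  if (length(out) == 1L) out <- c(out, out)  # degenerate single-facet input
  out
}

with_clean_outputs <- function(dir, expr) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tryCatch(expr, error = function(e) {
    unlink(dir, recursive = TRUE)
    stop(conditionMessage(e), call. = FALSE)
  })
}

screen_manifest <- function(config, results, common, loci, gene_calls) {
  th <- config$thresholds
  c(sprintf("promscreen_version: %s",
            as.character(utils::packageVersion("promscreen"))),
    sprintf("seed: %d", config$seed),
    sprintf("threshold_%s: %s", names(th),
            vapply(th, format, character(1))),
    sprintf("qc_threshold: %s", format(config$qc_threshold)),
    sprintf("excluded_samples: %s",
            if (length(config$exclude_samples))
              paste(config$exclude_samples, collapse = ",") else "none"),
    vapply(names(results), function(f) sprintf(
      "facet_%s: n_target=%d n_reference=%d n_specific=%d phi=%.6g",
      f, length(results[[f]]$target), length(results[[f]]$reference),
      sum(results[[f]]$records$specific), results[[f]]$phi), character(1)),
    sprintf("n_intersection: %d", length(common)),
    sprintf("n_loci: %d", length(loci)),
    sprintf("n_alternative_promoter_only: %d",
            sum(vapply(gene_calls, function(x)
              x$category == "alternative_promoter_only", logical(1)))))
}

#' Run the paired differentiation differential-expression pipeline
#'
#' Input (or paired-design simulation) -> sample exclusion -> RLE size
#' factors -> tpm -> paired NB differential expression between the two
#' states -> optional overlap with a provided specific promoter set ->
#' optional over-representation test of the up/down gene sets -> sample
#' clustering (average linkage, Spearman distance) -> export with a
#' manifest.
#'
#' @param config a [run_config()] with a [diff_sim_config()] simulation or
#'   real-data paths whose metadata carries `group` states and `donor_id`.
#' @return (invisibly) a result bundle: `diff_records`, `overlap`,
#'   `enrichment`, `sample_dendrogram`, `truth` (simulation only),
#'   `manifest`.
#' @export
run_differentiation_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)

  input <- run_stage("input", {
    if (!is.null(config$simulation)) {
      stopifnot(inherits(config$simulation, "diff_sim_config"))
      s <- simulate_differentiation(config$simulation)
      list(counts = s$matrix, sim = s)
    } else {
      list(counts = read_expression_table(config$expr_path, config$meta_path),
           sim = NULL)
    }
  })
  sim <- input$sim
  counts <- input$counts
  counts <- run_stage("exclusion",
                      drop_excluded(counts, config$exclude_samples))

  meta <- counts$sample_meta
  group_a <- meta$sample_id[meta$group == config$state_a]
  group_b <- meta$sample_id[meta$group == config$state_b]
  if (!length(group_a) || !length(group_b))
    stop("stage pairing: no samples with group '", config$state_a,
         "' or '", config$state_b, "'")

  sf <- run_stage("normalize", rle_size_factors(counts))
  tpm <- to_tpm(counts, sf)
  diff_records <- run_stage("differential", {
    rec <- differential_expression(
      tpm, counts, group_a, group_b, mode = "paired",
      fc_threshold = config$de_fc_threshold, alpha = config$de_alpha,
      pseudocount = config$de_pseudocount, size_factors = sf)
    log_stage("differential: %d up, %d down of %d promoters",
              sum(rec$call == "up"), sum(rec$call == "down"), nrow(rec))
    rec
  })

  specific_set <- run_stage("specific_set", {
    ss <- config$specific_set
    if (is.character(ss) && length(ss) == 1L && file.exists(ss)) {
      tab <- utils::read.delim(ss, colClasses = "character")
      if ("peak_id" %in% names(tab)) tab$peak_id else
        readLines(ss)
    } else ss
  })
  overlap <- if (!is.null(specific_set))
    run_stage("overlap", overlap_with_differential(specific_set,
                                                   diff_records))
  enrichment <- run_stage("enrichment", {
    cats <- config$categories
    if (is.character(cats) && length(cats) == 1L && file.exists(cats))
      cats <- yaml::read_yaml(cats)
    if (!is.null(cats)) {
      gene_map <- if (!is.null(sim)) sim$truth$gene_map else
        parse_promoter_id(diff_records$peak_id)[c("peak_id", "gene_symbol")]
      up_genes <- unique(stats::na.omit(gene_map$gene_symbol[
        match(diff_records$peak_id[diff_records$call == "up"],
              gene_map$peak_id)]))
      universe <- unique(stats::na.omit(gene_map$gene_symbol))
      enrichment_test(up_genes, cats, universe)
    }
  })

  dend <- run_stage("cluster", hierarchical_cluster(
    tpm, axis = "columns", distance = "spearman", linkage = "average"))

  manifest <- c(
    sprintf("promscreen_version: %s",
            as.character(utils::packageVersion("promscreen"))),
    sprintf("seed: %d", config$seed),
    sprintf("de_fc_threshold: %s", format(config$de_fc_threshold)),
    sprintf("de_alpha: %s", format(config$de_alpha)),
    sprintf("phi: %.6g", attr(diff_records, "phi")),
    sprintf("n_tested: %d", nrow(diff_records)),
    sprintf("n_up: %d", sum(diff_records$call == "up")),
    sprintf("n_down: %d", sum(diff_records$call == "down")),
    if (!is.null(overlap))
      sprintf("overlap: n_up=%d n_down=%d n_total=%d frac_up=%.4f",
              overlap$n_up, overlap$n_down, overlap$n_total,
              overlap$frac_up))

  if (!is.null(config$out_dir))
    run_stage("export", with_clean_outputs(config$out_dir, {
      export_report(diff_records = diff_records,
                    cluster_labels = cut_clusters(
                      dend, min(config$n_clusters,
                                length(dend$labels))),
                    tpm_matrix = tpm, dir = config$out_dir)
      write_results_table(diff_records,
                          file.path(config$out_dir, "differential_records.tsv"))
      if (!is.null(enrichment))
        write_results_table(enrichment,
                            file.path(config$out_dir, "enrichment.tsv"))
      writeLines(manifest, file.path(config$out_dir, "manifest.txt"))
    }))

  invisible(list(diff_records = diff_records, overlap = overlap,
                 enrichment = enrichment, sample_dendrogram = dend,
                 truth = if (!is.null(sim)) sim$truth, manifest = manifest))
}
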