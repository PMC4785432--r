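#' Pipeline configuration
#'
#' Collects every threshold of the integrated workflow, with the study's
#' conventions as defaults: gene DE at Bonferroni-adjusted p < 0.05,
#' miRNA DE at Benjamini--Hochberg FDR < 0.05, anticorrelation at
#' r < -0.5 and p < 0.05, enrichment FDR < 0.10, graphical-lasso penalty
#' rho = 0.03, 500 permutation repetitions for the GGM null and 999 for
#' the PCA Monte-Carlo test.
#'
#' @param gene_alpha,mirna_alpha DE significance levels.
#' @param r_max,p_max anticorrelation thresholds (`r_max` must be
#'   negative).
#' @param enrich_fdr enrichment FDR threshold.
#' @param rho graphical-lasso penalty constant.
#' @param n_rep GGM permutation repetitions.
#' @param n_perm PCA permutation replicates.
#' @param detect_min_fraction,detect_sd_multiplier detection-filter
#'   parameters.
#' @param paired fit DE on within-subject differences (default) or as a
#'   two-group model.
#' @param filter_before_normalize apply the detection filter to the raw
#'   rather than the normalized intensities.
#' @param seed master integer seed; per-stage streams are derived from
#'   it.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(gene_alpha = 0.05, mirna_alpha = 0.05,
                            r_max = -0.5, p_max = 0.05, enrich_fdr = 0.10,
                            rho = 0.03, n_rep = 500, n_perm = 999,
                            detect_min_fraction = 1 / 3,
                            detect_sd_multiplier = 1.5, paired = TRUE,
                            filter_before_normalize = FALSE, seed = 1L) {
  if (r_max >= 0)
    stop("validation error: r_max (anticorrelation threshold) must be negative")
  for (f in c("gene_alpha", "mirna_alpha", "p_max", "enrich_fdr"))
    if (get(f) <= 0 || get(f) >= 1)
      stop("validation error: ", f, " must lie in (0, 1)")
  if (rho < 0) stop("validation error: rho must be >= 0")
  if (n_rep < 1 || n_perm < 1)
    stop("validation error: repetition counts must be positive")
  structure(list(gene_alpha = gene_alpha, mirna_alpha = mirna_alpha,
                 r_max = r_max, p_max = p_max, enrich_fdr = enrich_fdr,
                 rho = rho, n_rep = n_rep, n_perm = n_perm,
                 detect_min_fraction = detect_min_fraction,
                 detect_sd_multiplier = detect_sd_multiplier,
                 paired = paired,
                 filter_before_normalize = filter_before_normalize,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage_seed <- function(seed, stage)
  as.integer((as.numeric(seed) * 10007 + stage) %% 2147483647)

#' Run the integrated miRNA--mRNA pipeline
#'
#' Executes preparation (quantile normalization and the miRNA detection
#' filter), differential expression of genes and miRNAs on the
#' experimental cohort, the PCA group-separation test, per-miRNA target
#' enrichment among anticorrelated DEGs, GGM validation of the enriched
#' miRNAs on each validation timepoint, and the PPI first-neighbour
#' subnetwork topology of the regulated genes. Every stage's table is
#' written to `run_dir` together with a flat key--value manifest holding
#' the thresholds, seed, and input checksums; two runs with the same
#' inputs and seed produce identical outputs.
#'
#' @param study an `expression_study`.
#' @param target_db a `target_db`.
#' @param ppi an igraph PPI network.
#' @param config a [pipeline_config()].
#' @param run_dir output directory (`NULL` to skip writing).
#' @return list with detected_mirnas, de_genes, de_mirnas, pca_gene,
#'   pca_mirna, enrichment, validation (per timepoint), network_topology,
#'   power_law, manifest.
#' @export
run_pipeline <- function(study, target_db, ppi, config = pipeline_config(),
                         run_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  rule <- detection_rule(config$detect_min_fraction,
                         config$detect_sd_multiplier)
  samples <- study$samples
  exp_samples <- samples[samples$cohort == "experimental", , drop = FALSE]

  # -- prep ----------------------------------------------------------------
  gm <- study$gene_matrix
  mm <- study$mirna_matrix
  if (config$filter_before_normalize) {
    det <- detection_filter(mm[, exp_samples$sample_id, drop = FALSE],
                            study$negctrl_mean, study$negctrl_sd, rule)
    mm <- quantile_normalize(mm[det, , drop = FALSE])
    gm <- quantile_normalize(gm)
  } else {
    gm <- quantile_normalize(gm)
    mm <- quantile_normalize(mm)
    det <- detection_filter(mm[, exp_samples$sample_id, drop = FALSE],
                            study$negctrl_mean, study$negctrl_sd, rule)
    mm <- mm[det, , drop = FALSE]
  }

  # -- differential expression (experimental cohort) -----------------------
  gx <- gm[, exp_samples$sample_id, drop = FALSE]
  mx <- mm[, exp_samples$sample_id, drop = FALSE]
  de_genes <- fit_moderated(gx, exp_samples, paired = config$paired,
                            alpha = config$gene_alpha,
                            adjust = "bonferroni")
  de_mirnas <- fit_moderated(mx, exp_samples, paired = config$paired,
                             alpha = config$mirna_alpha,
                             adjust = "benjamini_hochberg")
  pca_gene <- pca_group_test(gx, exp_samples$timepoint,
                             n_perm = config$n_perm,
                             seed = .stage_seed(config$seed, 1L))
  pca_mirna <- pca_group_test(mx, exp_samples$timepoint,
                              n_perm = config$n_perm,
                              seed = .stage_seed(config$seed, 2L))

  # -- target enrichment ---------------------------------------------------
  deg_ids <- de_genes$feature[de_genes$is_de]
  demirna_ids <- de_mirnas$feature[de_mirnas$is_de]
  de_pvalues <- setNames(de_genes$p, de_genes$feature)
  tested <- intersect(
    demirna_ids,
    names(target_db$targets)[vapply(target_db$targets, length,
                                    integer(1)) > 0])
  corr <- if (length(tested) > 0 && length(deg_ids) > 0)
    correlate_pairs(mx, gx, tested, deg_ids)
  else data.frame(mirna = character(0), gene = character(0),
                  r = numeric(0), p = numeric(0), degenerate = logical(0))
  enrich <- select_enriched(target_db, corr, deg_ids, de_pvalues,
                            universe_size = nrow(gm),
                            q = config$enrich_fdr, r_max = config$r_max,
                            p_max = config$p_max, mirna_ids = tested)
  enriched_ids <- enrich$table$mirna[enrich$table$enriched]

  # -- GGM validation on each validation timepoint -------------------------
  validation <- list()
  for (tp in c("T0", "T1")) {
    vs <- samples[samples$cohort == "validation" &
                    samples$timepoint == tp, , drop = FALSE]
    if (nrow(vs) < 6 || length(enriched_ids) == 0) next
    cand <- enrich$anticorr_targets[enriched_ids]
    cand <- cand[vapply(cand, length, integer(1)) > 0]
    if (length(cand) == 0) next
    validation[[tp]] <- validate_mirnas(
      gm[, vs$sample_id, drop = FALSE],
      mm[intersect(rownames(mm), names(cand)), vs$sample_id, drop = FALSE],
      cand, target_db, ppi, rho = config$rho, n_rep = config$n_rep,
      seed = .stage_seed(config$seed, 3L + (tp == "T1")))
  }

  # -- network topology of the regulated genes -----------------------------
  network_topology <- NULL; power_law <- NULL; subnet <- NULL
  if (length(enrich$regulated_genes) > 0) {
    seeds <- intersect(enrich$regulated_genes, igraph::V(ppi)$name)
    if (length(seeds) > 0) {
      subnet <- suppressWarnings(
        first_neighbor_subnetwork(ppi, enrich$regulated_genes))
      if (igraph::vcount(subnet) > 0) {
        network_topology <- topology_summary(subnet)
        dd <- network_topology$degree_distribution
        if (sum(dd$k > 0 & dd$count > 0) >= 2)
          power_law <- fit_power_law(dd)
      }
    }
  }

  manifest <- c(
    stage_order = "prep,de,enrich,ggm,network",
    seed = config$seed,
    gene_alpha = config$gene_alpha, mirna_alpha = config$mirna_alpha,
    r_max = config$r_max, p_max = config$p_max,
    enrich_fdr = config$enrich_fdr, rho = config$rho,
    n_rep = config$n_rep, n_perm = config$n_perm,
    paired = config$paired,
    n_genes = nrow(gm), n_mirnas_detected = nrow(mm),
    n_de_genes = sum(de_genes$is_de), n_de_mirnas = sum(de_mirnas$is_de),
    n_enriched = length(enriched_ids),
    n_regulated_genes = length(enrich$regulated_genes),
    gene_matrix_md5 = .matrix_md5(study$gene_matrix),
    mirna_matrix_md5 = .matrix_md5(study$mirna_matrix))

  res <- list(detected_mirnas = rownames(mm), de_genes = de_genes,
              de_mirnas = de_mirnas, pca_gene = pca_gene,
              pca_mirna = pca_mirna, enrichment = enrich,
              enriched_mirnas = enriched_ids, validation = validation,
              subnetwork = subnet, network_topology = network_topology,
              power_law = power_law, manifest = manifest)
  if (!is.null(run_dir)) .write_run(res, run_dir)
  res
}

.matrix_md5 <- function(m) {
  tf <- tempfile()
  on.exit(unlink(tf))
  write_matrix_tsv(m, tf)
  unname(tools::md5sum(tf))
}

.write_run <- function(res, run_dir) {
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    write.table(df, file.path(run_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  writeLines(res$detected_mirnas, file.path(run_dir, "detected_mirnas.txt"))
  wt(res$de_genes, "de_genes.tsv")
  wt(res$de_mirnas, "de_mirnas.tsv")
  wt(res$enrichment$table, "enrichment.tsv")
  for (tp in names(res$validation))
    wt(res$validation[[tp]], paste0("ggm_validation_", tp, ".tsv"))
  if (!is.null(res$subnetwork))
    write_sif(res$subnetwork, file.path(run_dir, "subnetwork.sif"))
  writeLines(paste(names(res$manifest), res$manifest, sep = "\t"),
             file.path(run_dir, "manifest.txt"))
  invisible(run_dir)
}
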