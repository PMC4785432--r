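#' Pairwise Pearson correlation between miRNA and gene expression
#'
#' Computes Pearson r and its two-sided t-based p-value for every
#' requested (miRNA, gene) pair over the shared sample columns.
#' Zero-variance features yield an undefined correlation; such pairs are
#' emitted with r = 0 and flagged degenerate.
#'
#' @param mirna_matrix,gene_matrix feature x sample matrices with
#'   identical column sets.
#' @param mirna_ids,gene_ids features to correlate (default: all rows).
#' @return data.frame: mirna, gene, r, p, degenerate.
#' @export
correlate_pairs <- function(mirna_matrix, gene_matrix,
                            mirna_ids = rownames(mirna_matrix),
                            gene_ids = rownames(gene_matrix)) {
  common <- intersect(colnames(mirna_matrix), colnames(gene_matrix))
  if (length(common) < 3) stop("need at least 3 shared samples")
  M <- t(mirna_matrix[mirna_ids, common, drop = FALSE])
  G <- t(gene_matrix[gene_ids, common, drop = FALSE])
  n <- length(common)
  sd_m <- apply(M, 2, sd); sd_g <- apply(G, 2, sd)
  r <- suppressWarnings(cor(M, G))
  deg <- outer(sd_m == 0, sd_g == 0, "|")
  r[deg | !is.finite(r)] <- 0
  df <- n - 2
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df)
  p[r^2 >= 1] <- 0
  p[deg] <- 1
  data.frame(mirna = rep(mirna_ids, times = length(gene_ids)),
             gene = rep(gene_ids, each = length(mirna_ids)),
             r = as.vector(r), p = as.vector(p),
             degenerate = as.vector(deg),
             stringsAsFactors = FALSE)
}

#' Genes anticorrelated with a miRNA
#'
#' Returns the differentially expressed genes whose correlation with the
#' given miRNA satisfies r < `r_max` and p < `p_max` (both strict).
#'
#' @param corr_table output of [correlate_pairs()].
#' @param mirna miRNA id.
#' @param deg_ids differentially expressed gene ids.
#' @param r_max correlation threshold (< 0).
#' @param p_max p-value threshold.
#' @return character vector of gene ids.
#' @export
anticorrelated_set <- function(corr_table, mirna, deg_ids,
                               r_max = -0.5, p_max = 0.05) {
  if (r_max >= 0) stop("r_max must be negative")
  sub <- corr_table[corr_table$mirna == mirna &
                      corr_table$gene %in% deg_ids &
                      corr_table$r < r_max & corr_table$p < p_max, ]
  sort(unique(sub$gene))
}

#' Hypergeometric target-enrichment p-value
#'
#' Upper-tail probability P(X >= k) for X hypergeometric with population
#' `universe_size`, `|targets|` successes, `|anticorr|` draws and observed
#' overlap k = |targets & anticorr|. miRNAs without any annotated target
#' are skipped (NA), not assigned p = 1.
#'
#' @param targets validated target gene ids of the miRNA.
#' @param anticorr anticorrelated DEG ids (the draw).
#' @param universe_size number of genes in the transcriptome universe.
#' @return upper-tail p-value, or NA if `targets` is empty.
#' @export
hypergeom_enrichment <- function(targets, anticorr, universe_size) {
  targets <- unique(targets); anticorr <- unique(anticorr)
  if (length(targets) == 0) return(NA_real_)
  if (universe_size < length(union(targets, anticorr)))
    stop("universe smaller than the union of targets and draws")
  k <- length(intersect(targets, anticorr))
  phyper(k - 1, length(targets), universe_size - length(targets),
         length(anticorr), lower.tail = FALSE)
}

#' Rank-based generalization of the hypergeometric enrichment test
#'
#' One-sided Wilcoxon rank-sum test of whether the miRNA's target genes
#' have stochastically smaller differential-expression p-values than the
#' rest of the universe. The exact null distribution is used when the
#' smaller group has at most 10 members and there are no ties; otherwise
#' the normal approximation with tie and continuity corrections applies.
#'
#' @param targets target gene ids (non-empty, a strict subset of the
#'   universe).
#' @param de_pvalues named vector of DE p-values covering the universe.
#' @return one-sided p-value.
#' @export
rank_enrichment <- function(targets, de_pvalues) {
  targets <- unique(targets)
  targets <- targets[targets %in% names(de_pvalues)]
  if (length(targets) == 0) return(NA_real_)
  other <- setdiff(names(de_pvalues), targets)
  if (length(other) == 0) stop("targets cover the whole universe")
  x <- de_pvalues[targets]; y <- de_pvalues[other]
  exact <- min(length(x), length(y)) <= 10 && !any(duplicated(c(x, y)))
  suppressWarnings(
    wilcox.test(x, y, alternative = "less", exact = exact,
                correct = TRUE)$p.value)
}

#' Select enriched miRNAs
#'
#' Benjamini--Hochberg adjusts the hypergeometric and rank-test p-value
#' families separately across the tested miRNAs, then flags a miRNA as
#' enriched when either FDR falls below `q` AND at least one of its
#' validated targets is anticorrelated (r < `r_max`, p < `p_max`) with it
#' among the DEGs. The union of anticorrelated target sets over the
#' enriched miRNAs is the pipeline's regulated-gene list.
#'
#' @param target_db a `target_db` (see [generate_target_db()] /
#'   [read_gmt()]).
#' @param corr_table output of [correlate_pairs()].
#' @param deg_ids differentially expressed gene ids.
#' @param de_pvalues named DE p-values over the gene universe (for the
#'   rank test).
#' @param universe_size gene universe size (default: length of
#'   `de_pvalues`).
#' @param q FDR threshold.
#' @param r_max,p_max anticorrelation thresholds.
#' @param mirna_ids miRNAs to test (default: all with non-empty targets).
#' @return list with `table` (per-miRNA data.frame: mirna, n_targets,
#'   n_anticorr_targets, p_hyper, p_rank, fdr_hyper, fdr_rank, enriched),
#'   `anticorr_targets` (named list of per-miRNA anticorrelated target
#'   ids) and `regulated_genes` (their union over enriched miRNAs).
#' @export
select_enriched <- function(target_db, corr_table, deg_ids, de_pvalues,
                            universe_size = length(de_pvalues), q = 0.10,
                            r_max = -0.5, p_max = 0.05,
                            mirna_ids = NULL) {
  tested <- names(target_db$targets)[vapply(target_db$targets, length,
                                            integer(1)) > 0]
  if (!is.null(mirna_ids)) tested <- intersect(tested, mirna_ids)
  tested <- intersect(tested, unique(corr_table$mirna))
  if (length(tested) == 0)
    return(list(table = data.frame(), anticorr_targets = list(),
                regulated_genes = character(0)))

  anti <- lapply(setNames(tested, tested), function(m)
    anticorrelated_set(corr_table, m, deg_ids, r_max, p_max))
  anti_targets <- lapply(setNames(tested, tested), function(m)
    intersect(target_db$targets[[m]], anti[[m]]))
  p_hyper <- vapply(tested, function(m)
    hypergeom_enrichment(target_db$targets[[m]], anti[[m]], universe_size),
    numeric(1))
  p_rank <- vapply(tested, function(m)
    rank_enrichment(target_db$targets[[m]], de_pvalues), numeric(1))
  fdr_hyper <- adjust_pvalues(p_hyper, "benjamini_hochberg")
  fdr_rank <- adjust_pvalues(p_rank, "benjamini_hochberg")
  n_anti <- vapply(anti_targets, length, integer(1))
  enriched <- (pmin(fdr_hyper, fdr_rank, na.rm = TRUE) < q) & n_anti >= 1
  enriched[is.na(enriched)] <- FALSE
  tab <- data.frame(
    mirna = tested,
    n_targets = vapply(target_db$targets[tested], length, integer(1)),
    n_anticorr_targets = n_anti,
    p_hyper = p_hyper, p_rank = p_rank,
    fdr_hyper = fdr_hyper, fdr_rank = fdr_rank,
    enriched = enriched, row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, anticorr_targets = anti_targets,
       regulated_genes = sort(unique(unlist(anti_targets[enriched]))))
}

#' Correlate per-subject miRNA changes with external covariates
#'
#' Pearson and Spearman correlations, with p-values, between each miRNA's
#' per-subject T1 - T0 change and each covariate. Constant inputs are
#' flagged degenerate (NA coefficients).
#'
#' @param mirna_deltas miRNA x subject matrix of T1 - T0 changes.
#' @param covariates subject x variable data.frame (rownames = subject
#'   ids).
#' @return data.frame: mirna, variable, pearson_r, pearson_p,
#'   spearman_rho, spearman_p, degenerate.
#' @export
correlate_covariates <- function(mirna_deltas, covariates) {
  subj <- intersect(colnames(mirna_deltas), rownames(covariates))
  if (length(subj) < 3) stop("need at least 3 shared subjects")
  out <- list()
  for (m in rownames(mirna_deltas)) {
    d <- mirna_deltas[m, subj]
    for (v in colnames(covariates)) {
      x <- covariates[subj, v]
      degen <- sd(d) == 0 || sd(x) == 0
      if (degen) {
        row <- data.frame(mirna = m, variable = v, pearson_r = NA_real_,
                          pearson_p = NA_real_, spearman_rho = NA_real_,
                          spearman_p = NA_real_, degenerate = TRUE)
      } else {
        pe <- cor.test(d, x, method = "pearson")
        sp <- suppressWarnings(cor.test(d, x, method = "spearman"))
        row <- data.frame(mirna = m, variable = v,
                          pearson_r = unname(pe$estimate),
                          pearson_p = pe$p.value,
                          spearman_rho = unname(sp$estimate),
                          spearman_p = sp$p.value, degenerate = FALSE)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
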