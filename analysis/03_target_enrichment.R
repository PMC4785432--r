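#!/usr/bin/env Rscript
# Stage 3 -- target enrichment among anticorrelated DEGs.
#
# For every DE miRNA with a non-empty targetome: pairwise Pearson
# correlation with the DEGs over the 28 experimental samples, the
# hypergeometric test on targets among anticorrelated DEGs (r < -0.5,
# p < 0.05), the rank-sum generalization over the DE p-values of the
# whole gene universe, BH adjustment per family, and the final rule
# (either FDR < 0.1 AND at least one anticorrelated target).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_config.R"))

inp <- read_study_inputs(INPUTS)
gm <- read_matrix_tsv(file.path(RESULTS, "genes_normalized.tsv"))
mm <- read_matrix_tsv(file.path(RESULTS, "mirnas_normalized.tsv"))
de_g <- read.delim(file.path(RESULTS, "de_genes.tsv"))
de_m <- read.delim(file.path(RESULTS, "de_mirnas.tsv"))
exps <- inp$study$samples[inp$study$samples$cohort == "experimental", ]

deg <- de_g$feature[de_g$is_de]
demir <- de_m$feature[de_m$is_de]
tested <- intersect(demir, names(inp$target_db$targets)[
  vapply(inp$target_db$targets, length, integer(1)) > 0])
msg("DE miRNAs with a targetome: %d / %d", length(tested), length(demir))

corr <- correlate_pairs(mm[, exps$sample_id], gm[, exps$sample_id],
                        tested, deg)
enr <- select_enriched(inp$target_db, corr, deg,
                       setNames(de_g$p, de_g$feature),
                       universe_size = nrow(gm), q = PIPE_CFG$enrich_fdr,
                       r_max = PIPE_CFG$r_max, p_max = PIPE_CFG$p_max,
                       mirna_ids = tested)
write.table(enr$table, file.path(RESULTS, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# miRNA -> anticorrelated-target edges, weighted by r
edges <- do.call(rbind, lapply(
  enr$table$mirna[enr$table$enriched], function(m) {
    tg <- enr$anticorr_targets[[m]]
    sub <- corr[corr$mirna == m & corr$gene %in% tg, ]
    data.frame(mirna = m, gene = sub$gene, r = sub$r)
  }))
write.table(edges, file.path(RESULTS, "anticorr_network.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(enr$regulated_genes, file.path(RESULTS, "regulated_genes.txt"))

msg("enriched miRNAs (FDR < %.2f, >= 1 anticorrelated target): %s",
    PIPE_CFG$enrich_fdr,
    paste(enr$table$mirna[enr$table$enriched], collapse = ", "))
msg("union of anticorrelated targets: %d genes",
    length(enr$regulated_genes))
truth <- inp$truth
msg("planted regulators recovered: %d / %d",
    sum(unlist(truth$regulator_ids) %in%
          enr$table$mirna[enr$table$enriched]),
    length(unlist(truth$regulator_ids)))
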