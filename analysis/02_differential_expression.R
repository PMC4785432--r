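#!/usr/bin/env Rscript
# Stage 2 -- preprocessing and differential expression.
#
# Quantile-normalizes both matrices, applies the negative-control
# detection filter to the miRNAs (mean + 1.5 SD, expressed in >= 1/3 of
# experimental samples), fits the paired moderated model per feature
# (genes: Bonferroni < 0.05; miRNAs: Benjamini-Hochberg < 0.05) and runs
# the PCA Monte-Carlo group-separation test with 999 permutations.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_config.R"))

inp <- read_study_inputs(INPUTS)
st <- inp$study
gm <- quantile_normalize(st$gene_matrix)
mm <- quantile_normalize(st$mirna_matrix)
exps <- st$samples[st$samples$cohort == "experimental", ]
det <- detection_filter(mm[, exps$sample_id], st$negctrl_mean,
                        st$negctrl_sd)
mm <- mm[det, ]
msg("detected miRNAs: %d / %d", length(det), nrow(st$mirna_matrix))

write_matrix_tsv(gm, file.path(RESULTS, "genes_normalized.tsv"))
write_matrix_tsv(mm, file.path(RESULTS, "mirnas_normalized.tsv"))

de_g <- fit_moderated(gm[, exps$sample_id], exps, paired = TRUE,
                      alpha = 0.05, adjust = "bonferroni")
de_m <- fit_moderated(mm[, exps$sample_id], exps, paired = TRUE,
                      alpha = 0.05, adjust = "benjamini_hochberg")
write.table(de_g, file.path(RESULTS, "de_genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(de_m, file.path(RESULTS, "de_mirnas.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
msg("DE genes (Bonferroni < 0.05): %d; DE miRNAs (BH < 0.05): %d",
    sum(de_g$is_de), sum(de_m$is_de))

pg <- pca_group_test(gm[, exps$sample_id], exps$timepoint,
                     n_perm = PIPE_CFG$n_perm, seed = SEED + 10)
pm <- pca_group_test(mm[, exps$sample_id], exps$timepoint,
                     n_perm = PIPE_CFG$n_perm, seed = SEED + 11)
msg("PCA between-group inertia: genes %.1f%% (p = %.3f), miRNAs %.1f%% (p = %.3f)",
    100 * pg$statistic, pg$p, 100 * pm$statistic, pm$p)
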