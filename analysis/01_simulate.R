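#!/usr/bin/env Rscript
# Stage 1 -- simulate the study.
#
# Generates the paired expression cohorts (14 experimental subjects at
# T0 and T1; 16 T0-only and 31 T1-only validation subjects) with five
# planted regulator miRNAs repressing ten targets each, the target
# annotation (1% decoy links), a random PPI network, and a small-RNA
# read set over five planted hairpin loci. Everything is written as
# plain text under results/inputs/.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_config.R"))

gs <- generate_study(STUDY_CFG)
db <- generate_target_db(rownames(gs$study$mirna_matrix),
                         rownames(gs$study$gene_matrix), gs$truth,
                         decoy_density = 0.01, seed = SEED + 1)
ppi <- generate_ppi(rownames(gs$study$gene_matrix), 0.002, seed = SEED + 2)
write_study_inputs(gs$study, gs$truth, db, ppi, INPUTS)

loci <- plant_hairpin_loci(5, 20000, seed = SEED + 3)
rs <- generate_read_set(loci, depth = 50, noise_reads = 200,
                        genome_length = 20000, seed = SEED + 4)
write_reads_bed(rs$reads, file.path(INPUTS, "reads.bed"))
Biostrings::writeXStringSet(rs$genome, file.path(INPUTS, "genome.fa"))
write.table(rs$loci, file.path(INPUTS, "planted_loci.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rs$alignments, file.path(INPUTS, "alignments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

msg("simulated %d genes x %d samples, %d miRNAs",
    nrow(gs$study$gene_matrix), ncol(gs$study$gene_matrix),
    nrow(gs$study$mirna_matrix))
msg("planted regulators: %s", paste(gs$truth$regulator_ids, collapse = ", "))
msg("planted hairpin loci: %d; reads: %d", nrow(rs$loci), nrow(rs$reads))
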