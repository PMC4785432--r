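#!/usr/bin/env Rscript
# Stage 5 -- novel miRNA prediction from mapped small-RNA reads.
#
# Filters the reads (length 17-27, < 2 mismatches, <= 6 alignments),
# clusters them into loci (>= 10 reads), finds each locus's highest
# local read stack (20-bp downstream jump rule), excises the two flanked
# precursor candidates (50/10 and 10/50) and screens each for a
# miRNA-like hairpin.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_config.R"))

reads <- read_reads_bed(file.path(INPUTS, "reads.bed"))
genome <- Biostrings::readDNAStringSet(file.path(INPUTS, "genome.fa"))
names(genome) <- sub(" .*", "", names(genome))
aligns <- read.delim(file.path(INPUTS, "alignments.tsv"))
planted <- read.delim(file.path(INPUTS, "planted_loci.tsv"))

found <- discover_mirnas(reads, genome, aligns, min_reads = 10,
                         max_gap = 10, mito_contig = NA)
write.table(found[, setdiff(names(found), "sequence")],
            file.path(RESULTS, "precursor_candidates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
fa <- Biostrings::DNAStringSet(found$sequence)
names(fa) <- sprintf("%s_%d_%d_%s", found$contig, found$cand_start,
                     found$cand_end, found$flank_mode)
Biostrings::writeXStringSet(fa, file.path(RESULTS, "precursors.fa"))

msg("candidate loci: %d; hairpin-passing candidates: %d",
    length(unique(found$locus_start)), sum(found$hairpin_pass))
rec <- vapply(seq_len(nrow(planted)), function(i)
  any(found$locus_start <= planted$mature_start[i] &
        found$locus_end >= planted$mature_start[i] & found$hairpin_pass),
  logical(1))
msg("planted loci recovered with a hairpin verdict: %d / %d",
    sum(rec), nrow(planted))
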