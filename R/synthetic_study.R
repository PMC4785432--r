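#' Configuration for a synthetic paired expression study
#'
#' Describes the cohort layout and the planted structure of a simulated
#' two-timepoint (T0 pre / T1 post) expression study profiling both mRNA and
#' miRNA on the same samples. Defaults mirror a paired design with 14
#' experimental subjects sampled at both timepoints plus an independent
#' validation cohort of 16 T0-only and 31 T1-only subjects.
#'
#' Planted regulator miRNAs are over-expressed at T1 and repress their
#' target genes proportionally to their own deviation from baseline, so
#' regulator--target pairs are negatively correlated across samples.
#'
#' @param n_genes,n_mirnas number of gene and miRNA features.
#' @param n_pairs_experimental paired subjects sampled at T0 and T1.
#' @param n_t0_validation,n_t1_validation validation subjects sampled at a
#'   single timepoint each.
#' @param frac_de_genes,frac_de_mirnas fraction of features with a planted
#'   T1 shift.
#' @param de_effect_size planted |log2 fold change| at T1.
#' @param n_planted_regulators number of miRNAs acting as repressors.
#' @param targets_per_regulator planted targets per regulator.
#' @param repression_strength slope (<= 0) linking a target to its
#'   regulator's deviation from baseline.
#' @param noise_sd independent log2-scale noise SD (> 0).
#' @param subject_sd SD of the per-subject, per-feature random intercept
#'   that correlates a subject's T0 and T1 samples.
#' @param negctrl_mean,negctrl_sd negative-control probe intensity summary
#'   used by the detection filter.
#' @param seed integer seed; the whole study is reproducible from it.
#' @return A validated `study_config` list.
#' @export
study_config <- function(n_genes = 2000, n_mirnas = 100,
                         n_pairs_experimental = 14,
                         n_t0_validation = 16, n_t1_validation = 31,
                         frac_de_genes = 0.10, frac_de_mirnas = 0.10,
                         de_effect_size = 2, n_planted_regulators = 5,
                         targets_per_regulator = 10,
                         repression_strength = -1, noise_sd = 0.5,
                         subject_sd = 0.5,
                         negctrl_mean = 6, negctrl_sd = 0.5, seed = 1L) {
  cfg <- list(n_genes = n_genes, n_mirnas = n_mirnas,
              n_pairs_experimental = n_pairs_experimental,
              n_t0_validation = n_t0_validation,
              n_t1_validation = n_t1_validation,
              frac_de_genes = frac_de_genes, frac_de_mirnas = frac_de_mirnas,
              de_effect_size = de_effect_size,
              n_planted_regulators = n_planted_regulators,
              targets_per_regulator = targets_per_regulator,
              repression_strength = repression_strength,
              noise_sd = noise_sd, subject_sd = subject_sd,
              negctrl_mean = negctrl_mean, negctrl_sd = negctrl_sd,
              seed = as.integer(seed))
  counts <- c("n_genes", "n_mirnas", "n_pairs_experimental",
              "n_t0_validation", "n_t1_validation", "n_planted_regulators",
              "targets_per_regulator")
  for (f in counts)
    if (cfg[[f]] < 0) stop("configuration error: ", f, " must be >= 0")
  for (f in c("frac_de_genes", "frac_de_mirnas"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("configuration error: ", f, " must lie in [0, 1]")
  if (cfg$noise_sd <= 0) stop("configuration error: noise_sd must be > 0")
  if (cfg$repression_strength > 0)
    stop("configuration error: repression_strength must be <= 0")
  if (cfg$targets_per_regulator > cfg$n_genes)
    stop("configuration error: targets_per_regulator exceeds n_genes")
  class(cfg) <- "study_config"
  cfg
}

#' Generate a synthetic paired miRNA--mRNA expression study
#'
#' Draws per-feature baselines from Normal(8, 2) on the log2 scale, adds a
#' per-subject random intercept, plants a signed `de_effect_size` shift at
#' T1 into a random fraction of features, over-expresses the planted
#' regulator miRNAs at T1 and propagates `repression_strength` times each
#' regulator's deviation from baseline into its target genes, then adds
#' independent Gaussian noise. Planted regulators are given well-expressed
#' baselines (Normal(10, 1)) so that they represent genuinely detectable
#' miRNAs rather than borderline probes.
#'
#' @param config a [study_config()].
#' @return A list with `study` (an `expression_study`: `gene_matrix`,
#'   `mirna_matrix`, `samples`, `negctrl_mean`, `negctrl_sd`) and `truth`
#'   (planted DE feature ids, regulator ids, regulator target map).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  gene_ids <- sprintf("gene%05d", seq_len(config$n_genes))
  mirna_ids <- sprintf("mir%04d", seq_len(config$n_mirnas))

  subj_exp <- sprintf("E%02d", seq_len(config$n_pairs_experimental))
  subj_v0 <- sprintf("V%02d", seq_len(config$n_t0_validation))
  subj_v1 <- sprintf("W%02d", seq_len(config$n_t1_validation))
  samples <- rbind(
    data.frame(subject_id = rep(subj_exp, each = 2),
               timepoint = rep(c("T0", "T1"), length(subj_exp)),
               cohort = "experimental", stringsAsFactors = FALSE),
    data.frame(subject_id = subj_v0, timepoint = "T0",
               cohort = "validation", stringsAsFactors = FALSE),
    data.frame(subject_id = subj_v1, timepoint = "T1",
               cohort = "validation", stringsAsFactors = FALSE))
  samples$sample_id <- paste0(samples$subject_id, "_", samples$timepoint)
  samples <- samples[, c("sample_id", "subject_id", "timepoint", "cohort")]
  n_s <- nrow(samples)
  subjects <- unique(samples$subject_id)

  n_de_g <- round(config$frac_de_genes * config$n_genes)
  n_de_m <- round(config$frac_de_mirnas * config$n_mirnas)
  de_genes <- sample(gene_ids, n_de_g)
  regulators <- if (config$n_planted_regulators > 0)
    sample(mirna_ids, config$n_planted_regulators) else character(0)
  de_mirnas <- unique(c(regulators,
                        sample(setdiff(mirna_ids, regulators),
                               max(0, n_de_m - length(regulators)))))

  # disjoint target sets when the gene pool allows it
  need <- config$n_planted_regulators * config$targets_per_regulator
  pool <- setdiff(gene_ids, de_genes)
  if (length(pool) < need) pool <- gene_ids
  picked <- sample(pool, min(need, length(pool)))
  regulator_targets <- list()
  if (length(regulators) > 0 && config$targets_per_regulator > 0) {
    idx <- split(seq_along(picked),
                 rep(seq_along(regulators), each = config$targets_per_regulator,
                     length.out = length(picked)))
    regulator_targets <- lapply(idx, function(i) picked[i])
    names(regulator_targets) <- regulators
  }

  base_g <- rnorm(config$n_genes, 8, 2)
  base_m <- rnorm(config$n_mirnas, 8, 2)
  names(base_g) <- gene_ids; names(base_m) <- mirna_ids
  base_m[regulators] <- rnorm(length(regulators), 10, 1)

  sign_g <- setNames(sample(c(-1, 1), config$n_genes, replace = TRUE), gene_ids)
  sign_m <- setNames(sample(c(-1, 1), config$n_mirnas, replace = TRUE), mirna_ids)
  sign_m[regulators] <- 1  # regulators over-expressed at T1

  is_t1 <- as.numeric(samples$timepoint == "T1")
  subj_idx <- match(samples$subject_id, subjects)

  build <- function(ids, base, de_ids, signs) {
    nf <- length(ids)
    b_subj <- matrix(rnorm(nf * length(subjects), 0, config$subject_sd),
                     nf, length(subjects), dimnames = list(ids, subjects))
    eff <- numeric(nf); names(eff) <- ids
    eff[de_ids] <- config$de_effect_size * signs[de_ids]
    m <- matrix(base, nf, n_s) + b_subj[, subj_idx] +
      outer(eff, is_t1) +
      matrix(rnorm(nf * n_s, 0, config$noise_sd), nf, n_s)
    dimnames(m) <- list(ids, samples$sample_id)
    m
  }
  mirna_matrix <- build(mirna_ids, base_m, de_mirnas, sign_m)
  gene_matrix <- build(gene_ids, base_g, de_genes, sign_g)

  # repression: each target tracks its regulator's deviation from baseline
  for (m in regulators) {
    dev <- mirna_matrix[m, ] - base_m[m]
    tg <- regulator_targets[[m]]
    if (length(tg) > 0)
      gene_matrix[tg, ] <- gene_matrix[tg, ] +
        matrix(config$repression_strength * dev, length(tg), n_s, byrow = TRUE)
  }

  study <- structure(
    list(gene_matrix = gene_matrix, mirna_matrix = mirna_matrix,
         samples = samples, negctrl_mean = config$negctrl_mean,
         negctrl_sd = config$negctrl_sd),
    class = "expression_study")
  truth <- list(de_gene_ids = sort(de_genes), de_mirna_ids = sort(de_mirnas),
                regulator_ids = regulators,
                regulator_targets = regulator_targets,
                planted_loci = list())
  list(study = study, truth = truth)
}

#' Generate a miRNA target annotation with decoy links
#'
#' Every planted regulator's true targets are always included; every other
#' (miRNA, gene) pair is added independently with probability
#' `decoy_density`. miRNAs can end up with empty target sets, emulating
#' real targetome databases in which many miRNAs have no validated target.
#'
#' @param mirna_ids,gene_ids feature id vectors (the gene ids define the
#'   annotation universe).
#' @param truth the `truth` component of [generate_study()] (or `NULL`).
#' @param decoy_density probability of a random decoy link, in \[0, 1\].
#' @param seed integer seed.
#' @return A `target_db`: list with `targets` (named list miRNA -> gene id
#'   character vector) and `universe` (gene ids).
#' @export
generate_target_db <- function(mirna_ids, gene_ids, truth = NULL,
                               decoy_density = 0.01, seed = 1L) {
  if (decoy_density < 0 || decoy_density > 1)
    stop("decoy_density must lie in [0, 1]")
  set.seed(as.integer(seed))
  planted <- if (is.null(truth)) list() else truth$regulator_targets
  targets <- lapply(setNames(mirna_ids, mirna_ids), function(m) {
    dec <- if (decoy_density >= 1) gene_ids
           else if (decoy_density <= 0) character(0)
           else gene_ids[runif(length(gene_ids)) < decoy_density]
    sort(unique(c(planted[[m]], dec)))
  })
  structure(list(targets = targets, universe = gene_ids), class = "target_db")
}

#' Generate a random protein--protein interaction network
#'
#' Erdos--Renyi G(n, p) graph over the gene ids: undirected, simple, no
#' self-loops.
#'
#' @param gene_ids node identifiers.
#' @param edge_density edge probability in \[0, 1\].
#' @param seed integer seed.
#' @return An [igraph::graph] with vertex names set to `gene_ids`.
#' @export
generate_ppi <- function(gene_ids, edge_density = 0.005, seed = 1L) {
  if (edge_density < 0 || edge_density > 1)
    stop("edge_density must lie in [0, 1]")
  set.seed(as.integer(seed))
  g <- igraph::sample_gnp(length(gene_ids), edge_density,
                          directed = FALSE, loops = FALSE)
  igraph::V(g)$name <- gene_ids
  g
}

#' Plant hairpin loci on a synthetic genome
#'
#' Lays out `n_loci` non-overlapping hairpin insertion sites on a single
#' contig, evenly spaced with jitter. Each locus spans
#' `2 * arm_len + loop_len` bases.
#'
#' @param n_loci number of loci.
#' @param genome_length contig length in bases.
#' @param contig contig name.
#' @param arm_len stem arm length (>= 20 so the stem screen is forced).
#' @param loop_len loop length (>= 4).
#' @param seed integer seed.
#' @return data.frame (contig, start, end, strand, arm_len, loop_len) with
#'   0-based half-open coordinates.
#' @export
plant_hairpin_loci <- function(n_loci, genome_length, contig = "chr1",
                               arm_len = 25, loop_len = 6, seed = 1L) {
  set.seed(as.integer(seed))
  locus_len <- 2 * arm_len + loop_len
  slot <- floor((genome_length - 200) / max(1, n_loci))
  if (slot < locus_len + 150)
    stop("configuration error: genome too short for the requested loci")
  start <- 100 + (seq_len(n_loci) - 1) * slot +
    sample.int(slot - locus_len - 120, n_loci, replace = TRUE)
  data.frame(contig = contig, start = start, end = start + locus_len,
             strand = "+", arm_len = arm_len, loop_len = loop_len,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic small-RNA read set over planted hairpins
#'
#' Builds a random genome, writes a perfect inverted repeat (stem =
#' `arm_len` >= 20 bp, loop >= 4 nt) at each planted locus, piles `depth`
#' reads on the mature (5') arm sharing the arm's 5' start so that they
#' form a read stack, and scatters `noise_reads` reads uniformly over the
#' genome. Per-read mismatch and alignment-count attributes are set (0--1
#' mismatches, a single alignment).
#'
#' @param loci data.frame from [plant_hairpin_loci()]; loci must not
#'   overlap.
#' @param depth reads piled on each planted mature arm.
#' @param noise_reads reads scattered uniformly over the genome.
#' @param genome_length contig length in bases.
#' @param seed integer seed.
#' @return list with `reads` (BED-like data.frame: contig, start, end,
#'   name, score, strand, mismatches, n_alignments), `genome`
#'   (a [Biostrings::DNAStringSet]), `alignments` (read name -> contig of
#'   each alignment) and `loci` (the input annotated with the planted
#'   mature interval).
#' @export
generate_read_set <- function(loci, depth = 50, noise_reads = 0,
                              genome_length = 10000, seed = 1L) {
  set.seed(as.integer(seed))
  contigs <- unique(loci$contig)
  if (any(loci$end > genome_length))
    stop("loci must lie within genome bounds")
  for (ct in contigs) {
    l <- loci[loci$contig == ct, , drop = FALSE]
    l <- l[order(l$start), , drop = FALSE]
    if (nrow(l) > 1 && any(l$start[-1] < l$end[-nrow(l)]))
      stop("configuration error: overlapping planted loci")
  }

  genome <- lapply(setNames(contigs, contigs), function(ct)
    sample(c("A", "C", "G", "T"), genome_length, replace = TRUE))

  revcomp <- function(x) rev(chartr("ACGT", "TGCA", x))
  loci$mature_start <- NA_integer_; loci$mature_end <- NA_integer_
  for (i in seq_len(nrow(loci))) {
    arm <- loci$arm_len[i]; loop <- loci$loop_len[i]
    left <- sample(c("A", "C", "G", "T"), arm, replace = TRUE)
    mid <- sample(c("A", "C", "G", "T"), loop, replace = TRUE)
    hp <- c(left, mid, revcomp(left))
    pos <- loci$start[i] + seq_along(hp)  # 1-based into the contig vector
    genome[[loci$contig[i]]][pos] <- hp
    loci$mature_start[i] <- loci$start[i]
    loci$mature_end[i] <- loci$start[i] + arm
  }

  reads <- list()
  aligns <- list()
  rid <- 0L
  emit <- function(contig, start, len, strand, mm, nal) {
    rid <<- rid + 1L
    nm <- sprintf("read%06d", rid)
    reads[[length(reads) + 1L]] <<- data.frame(
      contig = contig, start = start, end = start + len, name = nm,
      score = 0L, strand = strand, mismatches = mm, n_alignments = nal,
      stringsAsFactors = FALSE)
    aligns[[length(aligns) + 1L]] <<- data.frame(
      name = nm, contig = contig, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(loci))) {
    arm <- loci$arm_len[i]
    lens <- sample(seq(20, min(24, arm)), depth, replace = TRUE)
    for (len in lens)
      emit(loci$contig[i], loci$mature_start[i], len, loci$strand[i],
           sample(0:1, 1), 1L)
  }
  if (noise_reads > 0) {
    for (k in seq_len(noise_reads)) {
      len <- sample(17:27, 1)
      ct <- sample(contigs, 1)
      st <- sample.int(genome_length - len, 1) - 1L
      emit(ct, st, len, sample(c("+", "-"), 1), sample(0:1, 1), 1L)
    }
  }
  reads <- do.call(rbind, reads)
  genome_set <- Biostrings::DNAStringSet(
    vapply(genome, paste, character(1), collapse = ""))
  names(genome_set) <- contigs
  list(reads = reads, genome = genome_set,
       alignments = do.call(rbind, aligns), loci = loci)
}
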