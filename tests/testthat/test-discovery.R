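mk_reads <- function(starts, len = 22, contig = "chr1", strand = "+",
                     mm = 0, nal = 1) {
  data.frame(contig = contig, start = starts, end = starts + len,
             name = sprintf("r%04d", seq_along(starts)), score = 0L,
             strand = strand, mismatches = mm, n_alignments = nal,
             stringsAsFactors = FALSE)
}

test_that("read preprocessing applies every boundary rule", {
  r <- rbind(mk_reads(100, len = 16), mk_reads(200, len = 17),
             mk_reads(300, len = 27), mk_reads(400, len = 28))
  r$name <- sprintf("r%04d", 1:4)
  keep <- preprocess_reads(r)
  expect_setequal(keep$start, c(200, 300))

  r2 <- mk_reads(c(100, 200), len = 20)
  r2$mismatches <- c(1, 2)        # "fewer than 2" keeps only mm <= 1
  expect_equal(preprocess_reads(r2)$start, 100)

  r3 <- mk_reads(c(100, 200), len = 20)
  r3$n_alignments <- c(6, 7)
  expect_equal(preprocess_reads(r3)$start, 100)

  # any overlap with the ncRNA mask drops the read, even a single base
  r4 <- mk_reads(c(100, 200), len = 20)
  mask <- data.frame(contig = "chr1", start = 119, end = 150)
  expect_equal(preprocess_reads(r4, ncrna_mask = mask)$start, 200)
})

test_that("locus clustering enforces the 10-read rule and the gap", {
  expect_length(cluster_loci(mk_reads(rep(500, 12))), 1)
  expect_length(cluster_loci(mk_reads(rep(500, 9))), 0)
  two <- cluster_loci(mk_reads(c(rep(500, 12), rep(1000, 12))))
  expect_length(two, 2)
  # reads within the gap merge into one locus
  one <- cluster_loci(mk_reads(c(rep(500, 6), rep(530, 6))), max_gap = 10)
  expect_length(one, 1)
  expect_equal(one[[1]]$n_reads, 12)
  # opposite strands never merge
  r <- rbind(mk_reads(rep(500, 12), strand = "+"),
             mk_reads(rep(500, 12), strand = "-"))
  r$name <- sprintf("r%04d", 1:24)
  expect_length(cluster_loci(r), 2)
})

test_that("peak stack selection jumps downstream to higher stacks", {
  lc <- function(starts) cluster_loci(mk_reads(starts), min_reads = 1)[[1]]
  # higher stack within 20 bp downstream wins
  pk <- find_peak_stack(lc(c(rep(100, 15), rep(112, 30))))
  expect_equal(pk$stack_start, 112)
  expect_equal(pk$height, 30)
  # no higher stack downstream: stay
  pk2 <- find_peak_stack(lc(c(rep(100, 30), rep(112, 15))))
  expect_equal(pk2$stack_start, 100)
  # iterated chain 100(h5) -> 115(h10) -> 130(h20)
  pk3 <- find_peak_stack(lc(c(rep(100, 5), rep(115, 10), rep(130, 20))))
  expect_equal(pk3$stack_start, 130)
  expect_equal(pk3$height, 20)
})

test_that("excision arithmetic is strand-aware and clip-safe", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep("ACGT", 500), collapse = "")))
  cands <- excise_precursors("chr1", 1000, 1022, "+", genome)
  expect_equal(cands[[1]]$start, 950); expect_equal(cands[[1]]$end, 1032)
  expect_equal(cands[[2]]$start, 990); expect_equal(cands[[2]]$end, 1072)
  expect_equal(nchar(cands[[1]]$sequence), 22 + 60)
  expect_equal(nchar(cands[[2]]$sequence), 22 + 60)

  minus <- excise_precursors("chr1", 1000, 1022, "-", genome)
  expect_equal(minus[[1]]$start, 990); expect_equal(minus[[1]]$end, 1072)
  expect_equal(minus[[2]]$start, 950); expect_equal(minus[[2]]$end, 1032)
  fwd <- Biostrings::subseq(genome[["chr1"]], 991, 1072)
  expect_equal(minus[[1]]$sequence,
               as.character(Biostrings::reverseComplement(fwd)))

  clip <- excise_precursors("chr1", 30, 52, "+", genome)
  expect_equal(clip[[1]]$start, 0)
  expect_true(clip[[1]]$clipped)
  expect_error(excise_precursors("chrX", 10, 30, "+", genome), "absent")
})

test_that("hairpin screen passes perfect stems and fails homopolymers", {
  set.seed(1)
  arm <- paste(sample(c("A", "C", "G", "U"), 25, replace = TRUE),
               collapse = "")
  rc <- chartr("ACGU", "UGCA", paste(rev(strsplit(arm, "")[[1]]),
                                     collapse = ""))
  hp <- paste0(arm, "GAAA", rc)
  res <- hairpin_screen(hp)
  expect_true(res$pass)
  expect_equal(res$stem_len, 25)
  expect_lte(res$loop_len, 4)

  poly <- hairpin_screen(strrep("A", 60))
  expect_false(poly$pass)
  expect_equal(poly$stem_len, 0)
  expect_error(hairpin_screen(strrep("N", 50)), "non-nucleotide")
  expect_error(hairpin_screen("ACGU"), "shorter")
})

test_that("hairpin DP agrees with an independent recursion on random RNA", {
  set.seed(2)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "U"), 70, replace = TRUE),
               collapse = "")
    expect_equal(hairpin_screen(s)$stem_len, oracle_hairpin_stem(s))
  }
})

test_that("external folder plug-in overrides the built-in verdict", {
  seq50 <- strrep("A", 50)
  fold <- function(s) paste0(strrep("(", 20), strrep(".", 10),
                             strrep(")", 20))
  res <- hairpin_screen(seq50, folder = fold)
  expect_true(res$pass)
  expect_equal(res$stem_len, 20)
  expect_equal(res$loop_len, 10)
})

test_that("strand mirror symmetry preserves hairpin verdicts", {
  loci <- plant_hairpin_loci(2, 6000, seed = 13)
  rs <- generate_read_set(loci, depth = 30, noise_reads = 0,
                          genome_length = 6000, seed = 13)
  fwd <- discover_mirnas(rs$reads, rs$genome)
  # mirror the genome and the reads
  L <- length(rs$genome[["chr1"]])
  rc_genome <- Biostrings::DNAStringSet(
    c(chr1 = as.character(Biostrings::reverseComplement(rs$genome[["chr1"]]))))
  mr <- rs$reads
  mr$start <- L - rs$reads$end
  mr$end <- L - rs$reads$start
  mr$strand <- ifelse(rs$reads$strand == "+", "-", "+")
  rev <- discover_mirnas(mr, rc_genome)
  expect_equal(nrow(rev), nrow(fwd))
  expect_setequal(rev$hairpin_pass, fwd$hairpin_pass)
  expect_setequal(L - rev$stack_end, fwd$stack_start)
})

test_that("mitomiR calls require exclusively mitochondrial alignments", {
  lc <- cluster_loci(mk_reads(rep(100, 12), contig = "chrMT"))[[1]]
  al_pure <- data.frame(name = lc$reads$name, contig = "chrMT")
  expect_true(classify_mitomir(lc, al_pure, "chrMT"))
  al_mixed <- rbind(al_pure, data.frame(name = lc$reads$name[1],
                                        contig = "chr1"))
  expect_false(classify_mitomir(lc, al_mixed, "chrMT"))
  expect_warning(flag <- classify_mitomir(lc, al_pure, NA), "no mitochondrial")
  expect_false(flag)
})

test_that("low-depth loci are discarded and deep loci recovered end-to-end", {
  loci <- plant_hairpin_loci(2, 8000, seed = 14)
  shallow <- generate_read_set(loci, depth = 5, noise_reads = 0,
                               genome_length = 8000, seed = 14)
  expect_equal(nrow(discover_mirnas(shallow$reads, shallow$genome)), 0)

  deep <- generate_read_set(loci, depth = 50, noise_reads = 0,
                            genome_length = 8000, seed = 15)
  out <- discover_mirnas(deep$reads, deep$genome, deep$alignments)
  expect_equal(length(unique(out$locus_start)), 2)
  planted <- deep$loci
  for (i in seq_len(nrow(planted))) {
    hit <- out[out$stack_start == planted$mature_start[i] |
                 out$locus_start == planted$start[i], ]
    expect_true(any(hit$hairpin_pass))
    expect_true(all(hit$cand_end - hit$cand_start ==
                      (hit$stack_end - hit$stack_start) + 60))
  }
})
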