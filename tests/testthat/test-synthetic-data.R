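test_that("study generation is deterministic and structurally valid", {
  cfg <- study_config(n_genes = 200, n_mirnas = 20, seed = 7)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a, b)

  st <- a$study
  expect_identical(colnames(st$gene_matrix), st$samples$sample_id)
  expect_identical(colnames(st$mirna_matrix), st$samples$sample_id)
  exp_tab <- table(st$samples$subject_id[st$samples$cohort == "experimental"])
  expect_true(all(exp_tab == 2))
  expect_equal(sum(st$samples$cohort == "validation" &
                     st$samples$timepoint == "T0"), 16)
  expect_equal(sum(st$samples$cohort == "validation" &
                     st$samples$timepoint == "T1"), 31)
  expect_true(all(names(a$truth$regulator_targets) %in%
                    a$truth$regulator_ids))
})

test_that("configuration errors are rejected", {
  expect_error(study_config(noise_sd = 0), "noise_sd")
  expect_error(study_config(frac_de_genes = 1.5), "frac_de_genes")
  expect_error(study_config(targets_per_regulator = 500, n_genes = 100),
               "exceeds")
  expect_error(study_config(repression_strength = 0.5), "repression")
})

test_that("null configuration gives nominal downstream false-positive rate", {
  cfg <- study_config(n_genes = 2000, n_mirnas = 10, de_effect_size = 0,
                      repression_strength = 0, n_planted_regulators = 0,
                      frac_de_genes = 0, frac_de_mirnas = 0, seed = 42)
  gs <- generate_study(cfg)
  exps <- gs$study$samples[gs$study$samples$cohort == "experimental", ]
  de <- fit_moderated(gs$study$gene_matrix[, exps$sample_id], exps,
                      paired = TRUE)
  rate <- mean(de$p < 0.05)
  # binomial band around 0.05 for 2000 features (3 SE ~ 0.015)
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
})

test_that("planted regulators are strongly anticorrelated with their targets", {
  gs <- tiny_study(seed = 3, repression_strength = -1, noise_sd = 0.1)
  st <- gs$study
  exps <- st$samples$sample_id[st$samples$cohort == "experimental"]
  rs <- unlist(lapply(gs$truth$regulator_ids, function(m) {
    cor(st$mirna_matrix[m, exps],
        t(st$gene_matrix[gs$truth$regulator_targets[[m]], exps]))
  }))
  expect_gte(mean(rs < -0.5), 0.9)
})

test_that("increasing the planted effect never hurts DE sensitivity", {
  sens <- vapply(c(0.5, 1.5, 3), function(es) {
    mean(vapply(1:20, function(s) {
      gs <- generate_study(study_config(
        n_genes = 150, n_mirnas = 5, de_effect_size = es,
        n_planted_regulators = 0, frac_de_mirnas = 0, seed = 100 + s))
      exps <- gs$study$samples[gs$study$samples$cohort == "experimental", ]
      de <- fit_moderated(gs$study$gene_matrix[, exps$sample_id], exps)
      sum(de$is_de & de$feature %in% gs$truth$de_gene_ids) /
        length(gs$truth$de_gene_ids)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("target annotation honours decoy density", {
  gs <- tiny_study(seed = 5)
  mids <- rownames(gs$study$mirna_matrix)
  gids <- rownames(gs$study$gene_matrix)

  none <- generate_target_db(mids, gids, gs$truth, decoy_density = 0, seed = 2)
  for (m in mids) {
    planted <- gs$truth$regulator_targets[[m]]
    expect_setequal(none$targets[[m]],
                    if (is.null(planted)) character(0) else planted)
  }

  full <- generate_target_db(mids, gids, gs$truth, decoy_density = 1, seed = 2)
  expect_true(all(vapply(full$targets, length, integer(1)) == length(gids)))

  # decoy edges per miRNA ~ Binomial(n_genes, density)
  db <- generate_target_db(mids, gids, truth = NULL, decoy_density = 0.05,
                           seed = 9)
  counts <- vapply(db$targets, length, integer(1))
  expect_gt(mean(counts), qbinom(0.0005, length(gids), 0.05))
  expect_lt(mean(counts), qbinom(0.9995, length(gids), 0.05))
})

test_that("PPI generator respects edge density bounds", {
  ids <- sprintf("g%02d", 1:10)
  expect_equal(igraph::ecount(generate_ppi(ids, 0, seed = 1)), 0)
  expect_equal(igraph::ecount(generate_ppi(ids, 1, seed = 1)), 45)
  ec <- igraph::ecount(generate_ppi(ids, 0.2, seed = 3))
  expect_gte(ec, qbinom(0.0005, 45, 0.2))
  expect_lte(ec, qbinom(0.9995, 45, 0.2))
  g <- generate_ppi(ids, 0.5, seed = 4)
  expect_false(any(igraph::which_loop(g)))
  expect_false(any(igraph::which_multiple(g)))
})

test_that("read sets plant recoverable stacks and honest noise", {
  loci <- plant_hairpin_loci(2, 8000, seed = 11)
  rs <- generate_read_set(loci, depth = 40, noise_reads = 0,
                          genome_length = 8000, seed = 11)
  expect_true(all(rs$reads$end - rs$reads$start >= 17 &
                    rs$reads$end - rs$reads$start <= 27))
  expect_true(all(rs$reads$mismatches < 2))
  # planted hairpin is a perfect inverted repeat in the genome
  gseq <- strsplit(as.character(rs$genome[[1]]), "")[[1]]
  l1 <- loci[1, ]
  left <- gseq[(l1$start + 1):(l1$start + l1$arm_len)]
  right <- gseq[(l1$end - l1$arm_len + 1):l1$end]
  expect_identical(right, rev(chartr("ACGT", "TGCA", left)))

  over <- loci
  over$start[2] <- over$start[1] + 5
  over$end[2] <- over$start[2] + 56
  expect_error(generate_read_set(over, 10, 0, 8000, seed = 1), "overlapping")
})

test_that("scattered noise reads rarely form a 10-read cluster", {
  # dual route: package clustering vs a direct occupancy recount per seed
  hits <- 0L
  for (s in 1:10) {
    loci <- plant_hairpin_loci(1, 12000, seed = s)
    rs <- generate_read_set(loci, depth = 0, noise_reads = 200,
                            genome_length = 12000, seed = 200 + s)
    cl <- cluster_loci(rs$reads, max_gap = 10, min_reads = 10)
    # independent occupancy check: sort starts, single-linkage by hand
    for (key in unique(paste(rs$reads$contig, rs$reads$strand))) {
      sub <- rs$reads[paste(rs$reads$contig, rs$reads$strand) == key, ]
      sub <- sub[order(sub$start), ]
      sizes <- integer(0); cur <- 0L; cur_end <- -Inf
      for (i in seq_len(nrow(sub))) {
        if (sub$start[i] > cur_end + 10) {
          sizes <- c(sizes, cur); cur <- 1L; cur_end <- sub$end[i]
        } else {
          cur <- cur + 1L; cur_end <- max(cur_end, sub$end[i])
        }
      }
      sizes <- c(sizes, cur)
      keys <- vapply(cl, function(x) paste(x$contig, x$strand), character(1))
      expect_equal(sum(sizes >= 10), sum(keys == key))
    }
    hits <- hits + length(cl)
  }
  expect_lte(hits, 1L)
})
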