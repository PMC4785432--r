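# mirmint

Integrated miRNA–mRNA analysis for paired pre/post expression studies:
differential expression with empirical-Bayes moderation, per-miRNA target
enrichment among anticorrelated genes, validation of miRNA–target
networks on independent cohorts with zero-constrained graphical Gaussian
models, PPI subnetwork topology, and read-stack prediction of novel miRNA
precursors from mapped small-RNA reads.

## Who this is for

Transcriptomics groups that profile both the transcriptome and the
miRNome on the same samples before and after a perturbation (the
motivating design is a two-timepoint endurance-exercise study in the
horse: 14 paired experimental subjects plus an independent validation
cohort of 16 pre-only and 31 post-only subjects) and want to go from
expression matrices to a validated list of candidate regulatory miRNAs.

## The statistics at the core

- **Moderated differential expression.** Per feature, the timepoint
  effect is fit by least squares (paired mode: on within-subject
  T1 − T0 differences) and residual variances are shrunk with the
  empirical-Bayes posterior s²ₚₒₛₜ = (d₀s₀² + d s²)/(d₀ + d), the prior
  (d₀, s₀²) estimated by moment matching on log s²; the moderated t has
  d₀ + d degrees of freedom. Genes: Bonferroni < 0.05; miRNAs: BH < 0.05.
- **Target enrichment.** For each DE miRNA with a validated targetome,
  (i) an upper-tail hypergeometric test P(X ≥ k) of its targets among the
  DEGs anticorrelated with it (Pearson r < −0.5, p < 0.05), and (ii) a
  one-sided Wilcoxon rank-sum test of whether its targets' DE p-values
  are stochastically smaller than the rest of the universe. Each family
  is BH-adjusted; enriched = either FDR < 0.1 and ≥ 1 anticorrelated
  target.
- **Constrained graphical lasso.** maxΘ log det Θ − tr(SΘ) − ρΣ|Θᵢⱼ|
  subject to structural zeros (miRNA–miRNA always; miRNA–gene unless an
  annotated target; gene–gene unless a PPI edge), solved by blockwise
  coordinate descent with forbidden partners excluded from every lasso
  subproblem, so constrained entries are exactly zero. Each miRNA is
  predicted from its permitted neighbours by leave-one-out
  cross-validation (coefficients −Θᵢⱼ/Θⱼⱼ), and its MSE/R² are compared
  with 500 same-size random gene sets: permutation p = proportion of
  repetitions with smaller MSE (or larger R²).
- **Discovery heuristic.** Filtered reads (17–27 nt, < 2 mismatches,
  ≤ 6 alignments) are clustered (≥ 10 reads); the highest local 5'-start
  stack is found by iterated 20-bp downstream jumps; the stack is excised
  with 50/10 and 10/50 flanks and screened for a single-hairpin fold
  (stem ≥ 16 pairs, loop ≤ 20 nt).

## Worked example

The `analysis/` directory is a numbered, resumable workflow over a
synthetic study with five planted regulator miRNAs (repression slope −1,
noise SD 0.1). Running the stages in order:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_target_enrichment.R
Rscript analysis/04_ggm_validation.R
Rscript analysis/05_mirna_discovery.R
Rscript analysis/06_network_topology.R
```

prints, among other things:

```
planted regulators: mir0061, mir0089, mir0013, mir0014, mir0060
detected miRNAs: 79 / 100
DE genes (Bonferroni < 0.05): 332; DE miRNAs (BH < 0.05): 17
PCA between-group inertia: genes 33.3% (p = 0.001), miRNAs 29.6% (p = 0.001)
enriched miRNAs (FDR < 0.10, >= 1 anticorrelated target): mir0013, mir0014, mir0060, mir0061, mir0089
planted regulators recovered: 5 / 5
T1 cohort (n = 31): 4 miRNA(s) with permutation p_mse <= 0.05: mir0014, mir0060, mir0061, mir0089
planted loci recovered with a hairpin verdict: 5 / 5
degree distribution P(k) ~ 137.90 * k^-2.10 (R2 = 0.93)
```

Reading this: 21 of 100 simulated miRNAs fall below the negative-control
detection threshold; the paired moderated model recovers the planted DE
signal; the enrichment stage returns exactly the five planted regulators
(no decoy clears the FDR 0.10 + anticorrelation rule); the GGM stage
confirms them on the held-out cohorts via the random-gene permutation
null; all five planted hairpin loci are re-discovered from the read
pileups with no spurious candidate; and the regulated-gene PPI
subnetwork shows the heavy-tailed degree distribution typical of
first-neighbour extractions.

Tables land under `results/` (`de_genes.tsv`, `enrichment.tsv`,
`ggm_validation_T0.tsv`/`_T1.tsv`, `precursor_candidates.tsv`,
`topology.tsv`, …).

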