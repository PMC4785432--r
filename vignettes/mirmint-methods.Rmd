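---
title: "Integrated miRNA–mRNA analysis with mirmint: models and methods"
author: "mirmint authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated miRNA–mRNA analysis with mirmint: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mirmint` implements an integrated analysis of paired pre/post (T0/T1)
expression studies that profile the transcriptome and the miRNome on the
same blood samples: detection filtering and quantile normalization,
empirical-Bayes moderated differential expression, per-miRNA target
enrichment among anticorrelated differentially expressed genes (DEGs),
validation of candidate miRNA–target networks on independent cohorts with
zero-constrained graphical Gaussian models (GGMs), protein–protein
interaction (PPI) subnetwork topology, and a read-stack heuristic that
predicts novel miRNA precursors from genome-mapped small-RNA reads. A
synthetic-study generator produces every input with known ground truth, so
each stage can be tested end to end.

The numbered scripts under `analysis/` are thin drivers over the package
functions; they write their tables under `results/` and can be re-run
stage by stage.

# The synthetic study

`generate_study()` emulates a two-timepoint endurance-exercise design: 14
experimental subjects sampled at T0 and T1, plus an independent validation
cohort of 16 T0-only and 31 T1-only subjects. Per feature, the model on
the log2 scale is

$$x_{fs} = \mu_f + b_{f,\mathrm{subj}(s)} + \delta_f\,\mathbb{1}[s \in T1]
  + \varepsilon_{fs},$$

with baselines $\mu_f \sim N(8, 2)$ (a typical normalized-microarray
regime; the defaults are a modeling choice, not an estimate of any real
data set), a per-subject random intercept $b \sim N(0, 0.5)$ that
correlates a subject's two samples, a planted shift $|\delta_f| =$
`de_effect_size` (default 2 log2 units, random sign) for a
`frac_de_*` fraction of features, and independent noise
$\varepsilon \sim N(0, \texttt{noise\_sd})$. Planted regulator miRNAs are
forced over-expressed at T1, drawn with well-expressed baselines
$N(10, 1)$ (a regulator that fails its own detection filter would be a
contradiction in terms), and each target gene receives
`repression_strength` $\times$ (miRNA deviation from baseline), which
makes regulator–target pairs negatively correlated both within and across
timepoints. Negative-control probes are summarized as mean 6, SD 0.5, so
the detection threshold $6 + 1.5 \times 0.5 = 6.75$ sits inside the
baseline distribution and the filter has a non-trivial operating point.

What the generator does **not** emulate: probe-level images, dye and batch
effects, heavy-tailed intensity noise, correlated gene programs beyond the
planted regulator structure, and sequencing base quality. Passing tests
therefore demonstrate correctness of the statistical machinery under a
clean Gaussian design, not robustness to array artifacts.

`generate_target_db()` always includes the planted regulator→target links
and adds independent decoy links with probability `decoy_density`
(default 0.01), so many miRNAs have small or empty targetomes, as in real
validated-target databases. `generate_ppi()` is an Erdős–Rényi graph;
`generate_read_set()` writes perfect inverted repeats (stem 25 bp, loop
6 nt) into a random genome and piles reads on the mature arm sharing a 5'
start. Perfect repeats are a deliberate idealization: they make the
hairpin screen's acceptance analytically forced, so discovery tests
measure the bookkeeping (clustering, stack selection, excision
arithmetic), not folding heuristics.

# Preprocessing

`quantile_normalize()` maps every sample onto the across-sample mean of
the order statistics; tied values receive the mean of the reference
values over all their tied ranks (verified against
`limma::normalizeQuantiles`). The operation is idempotent.
`detection_filter()` calls a miRNA detected when its intensity is
strictly above the negative-control mean plus 1.5 SDs in at least one
third of the experimental samples; "at least 33%" is implemented as
fraction $\geq 1/3$ exactly, so 2 of 6 samples passes. The pipeline
filters after normalization by default (`filter_before_normalize`
switches the order; the original order is not documented in array
pipelines of this kind).

# Differential expression

`fit_moderated()` fits the timepoint effect per feature by least squares
and shrinks the residual variances with the standard empirical-Bayes
scheme: the prior $(d_0, s_0^2)$ is estimated by moment-matching a scaled
F distribution to the observed variances on the log scale (trigamma
inversion), the posterior variance is
$(d_0 s_0^2 + d s^2) / (d_0 + d)$, and the moderated t is referred to a
Student t with $d_0 + d$ degrees of freedom. When the log-variances show
no excess dispersion beyond chi-square sampling noise, the prior is a
point mass at the arithmetic mean of the variances ($d_0 = \infty$).
Because the design is paired, the default model is a one-sample fit on
within-subject T1 − T0 differences, which removes the subject intercept;
`paired = FALSE` reproduces the plain two-group fixed-effect model. Both
are exposed because the two are asymptotically equivalent only when the
subject intercept vanishes. Genes are adjusted by Bonferroni
(threshold 0.05), miRNAs by Benjamini–Hochberg (0.05), following the
convention that the gene family (tens of thousands of tests) warrants the
stricter control.

`pca_group_test()` measures the between-group fraction of the total
inertia of the sample cloud (the PCA rotation preserves sums of squares,
so the statistic is computed on the centered data directly) and assesses
it by label permutation with the add-one convention: with 999
permutations the smallest attainable p-value is 0.001.

# Target enrichment

For each DE miRNA with at least one annotated target, two complementary
tests ask whether its targetome is linked to the DE response:

* **Hypergeometric.** The anticorrelated set of a miRNA is the set of
  DEGs with Pearson $r < -0.5$ and $p < 0.05$ (both strict) against that
  miRNA over the 28 experimental samples (both timepoints pooled —
  pooling maximizes the exercise-driven covariation the $r < -0.5$ filter
  targets; per-subject deltas are available via `mirna_deltas`-style
  preprocessing). The test is the upper-tail probability
  $P(X \geq k)$ of the overlap between targets and the anticorrelated
  set, with the universe equal to all genes surviving preprocessing —
  not only the DEGs. miRNAs with empty targetomes are skipped, not
  assigned $p = 1$.
* **Rank generalization.** A one-sided Wilcoxon rank-sum test of whether
  the targets' DE p-values are stochastically smaller than those of the
  rest of the universe, which integrates over all possible significance
  thresholds and also captures targets regulated at the protein level.
  The exact null distribution is used when the smaller group has at most
  10 members and the values are tie-free; otherwise the normal
  approximation with tie and continuity corrections.

Each family is BH-adjusted separately across the tested miRNAs (the two
tests answer different questions and are reported with separate FDRs). A
miRNA is **enriched** when either FDR is below 0.10 — chosen permissive
to retain biological signal — *and* at least one of its validated
targets is itself anticorrelated; a miRNA significant by rank only, with
no strongly anticorrelated target, is excluded. The union of
anticorrelated target sets over enriched miRNAs is the regulated-gene
list passed downstream.

# GGM validation with structural zeros

On each validation cohort the package fits a graphical Gaussian model
over an enriched miRNA and its candidate genes, with three families of
edges constrained to exactly zero: miRNA–miRNA always, miRNA–gene unless
the gene is an annotated target, and gene–gene unless the pair is a PPI
edge. `fit_constrained_glasso()` maximizes

$$\log\det\Theta - \mathrm{tr}(S\Theta) - \rho \sum_{ij} |\Theta_{ij}|$$

subject to the structural zeros, by blockwise coordinate descent in which
forbidden partners are excluded from each column's lasso subproblem, so
forbidden entries are exactly zero rather than shrunk. The penalty
includes the diagonal (the working covariance starts at $S + \rho I$),
the convention under which the fully-shrunk fit has the closed form
$\Theta_{ii} = 1/(S_{ii} + \rho)$ and which matches the reference
graphical-lasso implementation this models. Convergence is declared when
the average absolute change of the working covariance per sweep falls
below $10^{-4}$ times the mean absolute off-diagonal of $S$ (default
`max_iter` 500, non-convergence flagged, never silent). Covariances are
maximum-likelihood ($1/n$) on column-centered data; during
cross-validation, centering always uses training-fold means.

The regression view gives the conditional mean of variable $j$:
coefficients $-\Theta_{ij}/\Theta_{jj}$. `cv_predict_mirna()` uses
leave-one-out (the validation cohorts have only 16 and 31 samples, so
k-fold schemes would be noisy), refits the constrained model on each
training fold and predicts the miRNA from all other variables. Two
criteria are recorded: the cross-validated MSE and $R^2$, the squared
Pearson correlation of predicted versus observed (the
$1 - SS_{res}/SS_{tot}$ alternative is available via `r2_method`).

One numerical subtlety deserves emphasis: the leave-one-out *mean*
predictor is perfectly anticorrelated with the held-out values
($\hat{y}_i = (n\bar{y} - y_i)/(n-1)$), so the squared-correlation
definition would read $R^2 = 1$ for a fit with no signal. The package
therefore defines $R^2 = 0$ whenever the miRNA has no permitted
neighbour or every regression coefficient is shrunk to zero in every
fold.

`select_rho()` picks the penalty by minimizing the mean leave-one-out MSE
over the miRNA nodes, breaking ties toward the larger (sparser) penalty;
the pipeline default is $\rho = 0.03$.

`permutation_validate()` draws, for each of `n_rep` (default 500)
repetitions, the same number of genes uniformly without replacement from
the whole transcriptome and applies literally the same procedure — the
drawn genes get their permitted edges from the same annotation lookup
(`mask_mode = "relabel"` instead transplants the candidate mask's
topology onto the drawn genes, provided because the procedure is
ambiguous on this point). The permutation p-values are plain proportions
(minimum 0): the fraction of repetitions with a smaller MSE, or a larger
$R^2$, than the candidate set. This deliberately differs from the
add-one convention of the PCA test, mirroring the respective original
procedures. BH adjustment is applied across miRNAs. Each miRNA receives
its own seed stream derived from the master seed, so adding or removing
one miRNA does not perturb the others.

A known limitation of the plain-proportion convention: when a miRNA's
candidate fit shrinks every coefficient to zero, its observed MSE exactly
ties the MSE of every empty-mask random repetition, ties do not count as
"smaller", and the p-value comes out spuriously small for a miRNA with no
signal at all. The add-one convention would remove the artifact, but the
plain proportion is the procedure being modeled; rankings in this package
break p-value ties by the observed MSE, and calibration checks are run in
regimes where candidate and random sets are exchangeable (every pool gene
annotated as a target), where the p-value is demonstrably uniform.

# Novel-miRNA discovery

Reads are kept when their length is within 17–27 nt, they carry fewer
than 2 mismatches, report at most 6 alignments, and do not overlap (by
any amount) a known-ncRNA mask. Strand-separated single-linkage
clustering merges reads within `max_gap = 10` bases (the gap is not
documented in the procedures this models; 10 bases keeps jittered 5'
ends together without bridging independent loci), and clusters with
fewer than 10 reads are discarded. A *stack* is the set of reads sharing
a 5' start — the biologically meaningful Drosha/Dicer anchor; on the
minus strand the 5' anchor is the right coordinate. Scanning 5'→3', the
pointer repeatedly jumps to any strictly higher stack whose anchor lies
within 20 bases downstream, until a fixed point: the highest local
stack. (The alternative literal reading — keep the *former*, lower stack
— contradicts the goal of identifying the highest local stack and is not
used.) The stack interval is excised twice with strand-aware flanks,
50 up / 10 down and 10 up / 50 down, modeling the 5p and 3p placements of
the mature arm; minus-strand candidates are reverse-complemented and
contig-edge clips are recorded.

The built-in hairpin screen is a structure-count dynamic program, not a
thermodynamic model: it maximizes the number of nested, non-branching
base pairs (Watson–Crick plus G·U, minimum loop 3 nt) — the
single-hairpin restriction is obtained simply by omitting the
bifurcation term of the classic pairing recursion — and passes a
candidate when the stem has at least 16 pairs and the loop at most 20 nt.
The thresholds are calibrated so that perfect planted hairpins always
pass and homopolymers always fail; random ~80-mers can pass, so the
screen is a filter on top of the ≥10-read clustering, not a stand-alone
detector. An external folding engine (e.g. an RNAfold-compatible tool)
can replace the verdict through the `folder` plug-in, which accepts any
function returning a dot-bracket string. MitomiR loci — all of whose
read alignments lie on the mitochondrial contig — are reported regardless
of the hairpin verdict, with the verdict attached.

# Network topology

`first_neighbor_subnetwork()` keeps the seed genes, their direct
neighbours, and only seed-incident edges (neighbour–neighbour edges are
excluded by default, reflecting a first-level interaction extraction; a
flag includes them). `topology_summary()` reports the degree
distribution, mean local clustering (degree < 2 contributes 0), mean
neighbourhood connectivity, the diameter of the largest component, edge
density, Freeman degree centralization, and degree heterogeneity defined
as the coefficient of variation of the degrees (population SD) — the
heterogeneity and centralization formulas follow the standard network
analyzer definitions since no others are documented. `fit_power_law()`
fits $P(k) = \beta k^a$ by least squares on $(\log_{10} k, \log_{10}
P(k))$ with $k = 0$ excluded — the log-log regression is a fidelity
choice matching the network-analyzer convention, not an endorsement of
least squares over maximum-likelihood power-law fitting.

# Pipeline and reproducibility

`run_pipeline()` wires the stages — preprocessing, DE, PCA tests,
enrichment, per-timepoint GGM validation of the enriched miRNAs, and the
regulated-gene subnetwork topology — under a single validated
configuration (gene Bonferroni 0.05, miRNA BH 0.05, $r < -0.5$,
$p < 0.05$, enrichment FDR 0.10, $\rho = 0.03$, 500 GGM repetitions, 999
PCA permutations). Per-stage seeds are derived from the master seed so
adding a stage never perturbs earlier stages' randomness; the manifest
is a flat key–value file holding thresholds, seeds, summary counts and
input checksums, and two runs with identical inputs and seed produce
byte-identical outputs.

# Problem sizes and numerical choices in the test suite

The test suite exercises the enumeration oracles exhaustively at small
sizes (hypergeometric universes up to 12; rank groups up to 5 × 7),
checks calibration with 10,000 simulated miRNAs (universe 10,000 with
5,000-gene target sets for the hypergeometric test, so that the discrete
achievable levels are dense near 0.05; universe 2,000 with 100-gene
targetomes for the rank test), verifies the constrained fit against a
restarted Nelder–Mead solver on 3×3 problems to within $10^{-6}$ in the
objective, recovers a known sparse precision at $n = 200$, $p = 20$,
tests permutation-null uniformity over 200 outer seeds at 100
repetitions, and runs the full pipeline at 2,000 genes × 100 miRNAs with
5 planted regulators. These sizes were chosen as the smallest at which
each property is statistically decidable; all statistical assertions use
pre-stated three-standard-error bands or Kolmogorov–Smirnov tests at
$p > 0.01$.

# Known limitations

* The enrichment correlation step pools T0 and T1 experimental samples;
  group-shift-driven correlation and within-subject covariation are not
  separated.
* The plain-proportion permutation p-value is biased toward significance
  for degenerate fits (see above).
* The built-in hairpin screen counts base pairs; it does not model
  thermodynamics, bulges asymmetry penalties or multiloops, and is
  expected to be permissive on long random sequences.
* The GGM stage assumes Gaussian expression on the log2 scale and
  annotation-faithful masks; a wrong targetome constrains true edges to
  zero and biases predictions pessimistically.
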