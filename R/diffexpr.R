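#' Invert the trigamma function
#'
#' Newton iteration on 1/trigamma, used by the empirical-Bayes
#' moment-matching estimator of the variance prior.
#'
#' @param x positive values.
#' @return y with trigamma(y) = x.
#' @keywords internal
trigamma_inverse <- function(x) {
  out <- x
  ok <- is.finite(x) & x > 0
  out[!ok & !is.na(x) & x <= 0] <- Inf
  y <- 0.5 + 1 / x[ok]
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x[ok]) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-8) break
  }
  out[ok] <- y
  out
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment-matches a scaled F / scaled inverse-chi-square distribution to
#' the observed residual variances `s2` with `d` residual degrees of
#' freedom, working on log(s2) so the estimator is robust to the skew of
#' the chi-square. Returns prior degrees of freedom `d0` (possibly
#' infinite) and prior variance `s0_sq`.
#'
#' @param s2 per-feature residual variances.
#' @param d residual degrees of freedom (scalar).
#' @keywords internal
estimate_moderation <- function(s2, d) {
  s2 <- s2[is.finite(s2)]
  if (all(s2 == 0)) {
    warning("zero residual variance everywhere; variance prior is a point mass")
    return(list(d0 = Inf, s0_sq = .Machine$double.eps))
  }
  s2 <- pmax(s2, 1e-12)
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion beyond chi-square sampling noise: the prior is
    # a point mass at the arithmetic mean of the variances
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated differential expression between T0 and T1
#'
#' Fits the timepoint effect per feature by least squares and shrinks the
#' residual variances with an empirical-Bayes prior: the posterior
#' variance is `(d0 * s0_sq + d * s2) / (d0 + d)` and the moderated t
#' statistic is referred to a Student t with `d0 + d` degrees of freedom.
#' In paired mode (the default, suited to subjects sampled at both
#' timepoints) the model is a one-sample fit on the within-subject
#' T1 - T0 differences; in unpaired mode it is a two-group comparison with
#' pooled variance, i.e. timepoint as the only fixed effect.
#'
#' @param mat features x samples matrix (log2 scale).
#' @param samples data.frame with columns sample_id, subject_id, timepoint
#'   (`"T0"`/`"T1"`); only samples present in `mat`'s columns are used.
#' @param paired fit on within-subject differences (default) or as a
#'   two-group model.
#' @param moderation `NULL` to estimate the prior from the data, or a list
#'   `list(d0 =, s0_sq =)` to fix it (`d0 = 0` recovers the ordinary t
#'   statistic, `d0 = Inf` uses the prior variance everywhere).
#' @param alpha significance level on the adjusted p-value.
#' @param adjust `"bonferroni"` or `"benjamini_hochberg"`.
#' @return data.frame: feature, effect (log2 FC, T1 - T0), t_mod, df, p,
#'   p_adj, is_de.
#' @export
fit_moderated <- function(mat, samples, paired = TRUE, moderation = NULL,
                          alpha = 0.05, adjust = "bonferroni") {
  mat <- as.matrix(mat)
  samples <- samples[samples$sample_id %in% colnames(mat), , drop = FALSE]
  if (!all(c("T0", "T1") %in% samples$timepoint))
    stop("both timepoints must be present")

  if (paired) {
    subj <- unique(samples$subject_id)
    s0 <- samples$sample_id[match(paste0(subj, ".T0"),
                                  paste0(samples$subject_id, ".", samples$timepoint))]
    s1 <- samples$sample_id[match(paste0(subj, ".T1"),
                                  paste0(samples$subject_id, ".", samples$timepoint))]
    keep <- !is.na(s0) & !is.na(s1)
    if (sum(keep) < 2) stop("paired fit needs at least 2 complete subjects")
    D <- mat[, s1[keep], drop = FALSE] - mat[, s0[keep], drop = FALSE]
    n <- ncol(D)
    effect <- rowMeans(D)
    s2 <- apply(D, 1, var)
    d <- n - 1
    se_unit <- sqrt(1 / n)
  } else {
    c0 <- samples$sample_id[samples$timepoint == "T0"]
    c1 <- samples$sample_id[samples$timepoint == "T1"]
    if (length(c0) < 2 || length(c1) < 2)
      stop("each timepoint needs at least 2 samples")
    m0 <- mat[, c0, drop = FALSE]; m1 <- mat[, c1, drop = FALSE]
    effect <- rowMeans(m1) - rowMeans(m0)
    ss <- apply(m0, 1, var) * (length(c0) - 1) +
      apply(m1, 1, var) * (length(c1) - 1)
    d <- length(c0) + length(c1) - 2
    s2 <- ss / d
    se_unit <- sqrt(1 / length(c0) + 1 / length(c1))
  }

  if (is.null(moderation)) moderation <- estimate_moderation(s2, d)
  d0 <- moderation$d0; s0_sq <- moderation$s0_sq
  if (d0 < 0 || s0_sq <= 0) stop("invalid moderation parameters")
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
             else (d0 * s0_sq + d * s2) / (d0 + d)
  df_total <- d0 + d
  t_mod <- effect / (sqrt(s2_post) * se_unit)
  p <- 2 * pt(-abs(t_mod), df = df_total)
  method <- match.arg(adjust, c("bonferroni", "benjamini_hochberg"))
  p_adj <- adjust_pvalues(p, method)
  data.frame(feature = rownames(mat), effect = effect, t_mod = t_mod,
             df = df_total, p = p, p_adj = p_adj, is_de = p_adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multiple-testing adjustment
#'
#' @param p raw p-values in \[0, 1\].
#' @param method `"bonferroni"` (min(1, m p)) or `"benjamini_hochberg"`
#'   (step-up FDR).
#' @return adjusted p-values, element-wise >= the raw ones.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "benjamini_hochberg")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = if (method == "bonferroni") "bonferroni" else "BH")
}

#' PCA group-separation test by Monte-Carlo permutation
#'
#' The statistic is the between-group fraction of the total inertia of the
#' sample scores (equivalently, of the column-centered data, since the PCA
#' rotation preserves sums of squares). Group labels are permuted over
#' samples; the p-value uses the add-one convention, so with 999
#' permutations the attainable minimum is 0.001.
#'
#' @param mat features x samples matrix.
#' @param groups factor-like group label per sample (>= 2 groups, each
#'   with >= 2 samples).
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return list(statistic, p, n_perm).
#' @export
pca_group_test <- function(mat, groups, n_perm = 999, seed = 1L) {
  mat <- as.matrix(mat)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  X <- t(mat - rowMeans(mat))  # samples x features, feature-centered
  sst <- sum(X^2)
  bss <- function(g) {
    gm <- rowsum(X, g) / as.vector(table(g))
    sum(as.vector(table(g)) * rowSums(gm^2))
  }
  if (sst == 0) return(list(statistic = 0, p = 1, n_perm = n_perm))
  obs <- bss(groups) / sst
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm),
                 function(i) bss(sample(groups)) / sst, numeric(1))
  list(statistic = obs, p = (sum(perm >= obs) + 1) / (n_perm + 1),
       n_perm = n_perm)
}
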