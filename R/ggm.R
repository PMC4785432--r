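#' Build the structural-zero mask for a miRNA--gene graphical model
#'
#' Permitted edges: miRNA--gene only when the gene is an annotated target
#' of the miRNA; gene--gene only when the pair is an edge of the PPI
#' network; miRNA--miRNA never. The diagonal is always free.
#'
#' @param mirna_ids,gene_ids variable ids (disjoint); the mask covers them
#'   in this order.
#' @param target_db a `target_db` (may be `NULL` for no miRNA--gene
#'   edges).
#' @param ppi an igraph PPI network (may be `NULL` for no gene--gene
#'   edges).
#' @return logical matrix (TRUE = permitted) with attribute `n_free`, the
#'   number of permitted off-diagonal pairs.
#' @export
build_zero_mask <- function(mirna_ids, gene_ids, target_db = NULL,
                            ppi = NULL) {
  if (length(intersect(mirna_ids, gene_ids)) > 0)
    stop("miRNA and gene id sets must be disjoint")
  ids <- c(mirna_ids, gene_ids)
  p <- length(ids)
  mask <- matrix(FALSE, p, p, dimnames = list(ids, ids))
  diag(mask) <- TRUE
  if (!is.null(target_db)) {
    for (m in intersect(mirna_ids, names(target_db$targets))) {
      tg <- intersect(target_db$targets[[m]], gene_ids)
      mask[m, tg] <- TRUE
      mask[tg, m] <- TRUE
    }
  }
  if (!is.null(ppi) && igraph::ecount(ppi) > 0) {
    el <- igraph::as_edgelist(ppi)
    keep <- el[, 1] %in% gene_ids & el[, 2] %in% gene_ids
    el <- el[keep, , drop = FALSE]
    if (nrow(el) > 0) {
      mask[el] <- TRUE
      mask[el[, c(2, 1), drop = FALSE]] <- TRUE
    }
  }
  attr(mask, "n_free") <- sum(mask[upper.tri(mask)])
  mask
}

#' Fit a graphical lasso with structural zeros
#'
#' Maximizes `log det(Theta) - tr(S Theta) - rho * sum |Theta_ij|` subject
#' to `Theta_ij = 0` on every entry forbidden by the mask, by blockwise
#' coordinate descent in which forbidden partners are excluded from each
#' column's lasso subproblem (so forbidden entries are exactly zero, not
#' merely shrunk). The penalty includes the diagonal, i.e. the working
#' covariance is initialized at `S + rho I`; with `rho = 0` and a full
#' mask the fit converges to `solve(S)`.
#'
#' @param S sample covariance matrix (symmetric positive semi-definite).
#' @param rho lasso penalty constant (>= 0).
#' @param mask logical matrix of permitted entries (see
#'   [build_zero_mask()]); `NULL` permits everything.
#' @param tol convergence tolerance on the average absolute change of the
#'   working covariance per sweep, scaled by mean |S_ij|.
#' @param max_iter maximum number of outer sweeps.
#' @return list of class `ggm_fit`: theta, w, rho, converged, n_iter.
#' @export
fit_constrained_glasso <- function(S, rho, mask = NULL, tol = 1e-4,
                                   max_iter = 500) {
  S <- as.matrix(S)
  if (rho < 0) stop("rho must be >= 0")
  p <- nrow(S)
  if (is.null(mask)) mask <- matrix(TRUE, p, p)
  mask <- as.matrix(mask)
  if (!isTRUE(all.equal(mask, t(mask)))) stop("mask must be symmetric")
  fit <- cglasso_cpp(S, rho, matrix(as.integer(mask), p, p), tol,
                     as.integer(max_iter))
  if (!fit$converged)
    warning("constrained glasso did not converge in ", max_iter, " sweeps")
  dimnames(fit$theta) <- dimnames(S)
  dimnames(fit$w) <- dimnames(S)
  fit$rho <- rho
  class(fit) <- "ggm_fit"
  fit
}

#' Penalized log-likelihood objective of a constrained glasso fit
#'
#' @param theta precision matrix.
#' @param S sample covariance.
#' @param rho penalty constant.
#' @return `log det(theta) - tr(S theta) - rho * sum |theta_ij|` (the
#'   penalty runs over all entries, diagonal included).
#' @export
glasso_objective <- function(theta, S, rho) {
  ld <- determinant(theta, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  as.numeric(ld$modulus) - sum(S * theta) - rho * sum(abs(theta))
}

#' Regression view of a Gaussian graphical model
#'
#' The conditional expectation of variable `j` given the others has
#' coefficients `-theta_ij / theta_jj`; a structurally zero precision
#' entry therefore yields a zero regression coefficient.
#'
#' @param theta precision matrix.
#' @param j index (or name) of the response variable.
#' @param means optional training means, to compute the intercept.
#' @return list(coef = named coefficient vector over the other variables,
#'   intercept).
#' @export
precision_to_regression <- function(theta, j, means = NULL) {
  if (is.character(j)) j <- match(j, rownames(theta))
  if (theta[j, j] <= 0) stop("theta_jj must be positive")
  beta <- -theta[-j, j] / theta[j, j]
  intercept <- if (is.null(means)) 0
               else unname(means[j] - sum(beta * means[-j]))
  list(coef = beta, intercept = intercept)
}

# MLE (1/n) covariance of column-centered data; centering means returned
.center_cov <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  list(S = crossprod(Xc) / nrow(X), mu = mu)
}

#' Leave-one-out prediction of a miRNA from its permitted neighbours
#'
#' For each held-out sample the constrained GGM is refit on the remaining
#' samples (centered by training-fold means, MLE covariance) and the
#' miRNA's value is predicted through the regression view of the fitted
#' precision matrix. A miRNA with no permitted neighbour is predicted by
#' the training mean and gets `r2 = 0` by definition.
#'
#' @param data samples x variables matrix.
#' @param mask structural-zero mask over the variables.
#' @param rho penalty constant.
#' @param mirna response variable (name or index).
#' @param r2_method squared Pearson correlation of predicted vs observed
#'   (default) or `"one_minus_ss"` for 1 - SSres/SStot.
#' @return list(mse, r2, predicted, observed).
#' @export
cv_predict_mirna <- function(data, mask, rho, mirna,
                             r2_method = c("cor", "one_minus_ss")) {
  r2_method <- match.arg(r2_method)
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < 5) stop("need at least 5 samples for leave-one-out validation")
  if (is.character(mirna)) mirna <- match(mirna, colnames(data))
  free <- which(mask[, mirna] & seq_len(ncol(data)) != mirna)
  pred <- numeric(n)
  any_coef <- FALSE
  for (i in seq_len(n)) {
    tr <- data[-i, , drop = FALSE]
    cc <- .center_cov(tr)
    if (length(free) == 0) {
      pred[i] <- cc$mu[mirna]
    } else {
      fit <- fit_constrained_glasso(cc$S, rho, mask)
      reg <- precision_to_regression(fit$theta, mirna, cc$mu)
      if (any(reg$coef != 0)) any_coef <- TRUE
      pred[i] <- reg$intercept + sum(reg$coef * data[i, -mirna])
    }
  }
  obs <- data[, mirna]
  mse <- mean((pred - obs)^2)
  # a null fit (no permitted neighbours, or every coefficient shrunk to
  # zero in every fold) has r2 = 0 by definition: its leave-one-out
  # predictions are the training means, which are perfectly anticorrelated
  # with the held-out values, so the squared correlation would read 1
  r2 <- if (!any_coef || sd(pred) == 0 || sd(obs) == 0) 0
        else if (r2_method == "cor") cor(pred, obs)^2
        else 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  list(mse = mse, r2 = r2, predicted = pred, observed = obs)
}

#' Select the lasso penalty by cross-validated MSE
#'
#' `rho*` minimizes the mean leave-one-out MSE over all miRNA nodes; ties
#' are broken toward the larger (sparser) penalty.
#'
#' @param data samples x variables matrix.
#' @param mask structural-zero mask.
#' @param grid candidate penalties (non-empty).
#' @param mirna_ids miRNA node names scored by the criterion.
#' @return list(rho, cv_mse = named vector over the grid).
#' @export
select_rho <- function(data, mask, grid, mirna_ids) {
  if (length(grid) == 0) stop("empty rho grid")
  grid <- sort(grid)
  cv <- vapply(grid, function(r)
    mean(vapply(mirna_ids,
                function(m) cv_predict_mirna(data, mask, r, m)$mse,
                numeric(1))),
    numeric(1))
  names(cv) <- grid
  best <- max(which(cv == min(cv)))  # ties -> larger rho
  list(rho = grid[best], cv_mse = cv)
}

#' Permutation validation of a miRNA's candidate gene set
#'
#' The observed leave-one-out MSE and R2 of predicting the miRNA from its
#' candidate genes (under the structural-zero mask induced by the target
#' annotation and the PPI network) are compared with `n_rep` repetitions
#' in which the same number of genes is drawn uniformly without
#' replacement from the gene pool and the identical procedure is applied.
#' The permutation p-values are plain proportions (minimum 0):
#' `p_mse = #(mse_rand < mse_obs) / n_rep` and
#' `p_r2 = #(r2_rand > r2_obs) / n_rep`.
#'
#' @param gene_expr genes x samples expression matrix (the random-gene
#'   pool).
#' @param mirna_expr named numeric vector: the miRNA's expression over the
#'   same samples.
#' @param mirna miRNA id.
#' @param candidate_genes the candidate gene set (subset of
#'   `rownames(gene_expr)`, smaller than the pool).
#' @param target_db,ppi annotations used to build each repetition's mask
#'   ("lookup" mode applies the same annotation lookup to the drawn
#'   genes); in `mask_mode = "relabel"` the candidate mask's topology is
#'   relabelled onto the drawn genes instead.
#' @param rho penalty constant.
#' @param n_rep number of random repetitions (> 0).
#' @param seed integer seed.
#' @param mask_mode `"lookup"` (default) or `"relabel"`.
#' @return list(mse, r2, p_mse, p_r2, n_rep, mse_rand, r2_rand).
#' @export
permutation_validate <- function(gene_expr, mirna_expr, mirna,
                                 candidate_genes, target_db, ppi, rho,
                                 n_rep = 500, seed = 1L,
                                 mask_mode = c("lookup", "relabel")) {
  mask_mode <- match.arg(mask_mode)
  if (n_rep <= 0) stop("n_rep must be positive")
  pool <- rownames(gene_expr)
  if (length(pool) <= length(candidate_genes))
    stop("gene pool must be larger than the candidate set")
  samples <- colnames(gene_expr)
  run_one <- function(genes, relabel_from = NULL) {
    dat <- cbind(mirna_expr[samples], t(gene_expr[genes, samples,
                                                  drop = FALSE]))
    colnames(dat)[1] <- mirna
    if (is.null(relabel_from)) {
      msk <- build_zero_mask(mirna, genes, target_db, ppi)
    } else {
      msk <- relabel_from
      dimnames(msk) <- list(c(mirna, genes), c(mirna, genes))
    }
    cv <- cv_predict_mirna(dat, msk, rho, mirna)
    c(cv$mse, cv$r2)
  }
  obs_mask <- build_zero_mask(mirna, candidate_genes, target_db, ppi)
  obs <- run_one(candidate_genes)
  set.seed(as.integer(seed))
  rand <- vapply(seq_len(n_rep), function(i) {
    g <- sample(pool, length(candidate_genes))
    run_one(g, relabel_from = if (mask_mode == "relabel") obs_mask else NULL)
  }, numeric(2))
  list(mse = obs[1], r2 = obs[2],
       p_mse = mean(rand[1, ] < obs[1]),
       p_r2 = mean(rand[2, ] > obs[2]),
       n_rep = n_rep, mse_rand = rand[1, ], r2_rand = rand[2, ])
}

#' Validate a set of miRNAs on a cohort with the permutation null
#'
#' Runs [permutation_validate()] for each miRNA against its candidate
#' gene set and Benjamini--Hochberg adjusts the permutation p-values
#' across miRNAs. Each miRNA gets its own seed stream derived from
#' `seed`, so adding or removing a miRNA does not perturb the others.
#'
#' @param gene_expr genes x samples cohort expression (the random pool).
#' @param mirna_expr miRNAs x samples cohort expression.
#' @param candidates named list miRNA -> candidate gene ids.
#' @param target_db,ppi annotations for the structural-zero masks.
#' @param rho penalty constant.
#' @param n_rep permutation repetitions per miRNA.
#' @param seed master integer seed.
#' @return data.frame: mirna, n_candidates, mse, r2, p_mse, p_r2,
#'   fdr_mse, fdr_r2.
#' @export
validate_mirnas <- function(gene_expr, mirna_expr, candidates, target_db,
                            ppi, rho = 0.03, n_rep = 500, seed = 1L) {
  mirnas <- names(candidates)
  res <- lapply(seq_along(mirnas), function(i) {
    m <- mirnas[i]
    pv <- permutation_validate(
      gene_expr, mirna_expr[m, ], m, candidates[[m]], target_db, ppi,
      rho, n_rep,
      seed = as.integer((as.numeric(seed) * 1009 + i) %% 2147483647))
    data.frame(mirna = m, n_candidates = length(candidates[[m]]),
               mse = pv$mse, r2 = pv$r2, p_mse = pv$p_mse,
               p_r2 = pv$p_r2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr_mse <- adjust_pvalues(out$p_mse, "benjamini_hochberg")
  out$fdr_r2 <- adjust_pvalues(out$p_r2, "benjamini_hochberg")
  out
}
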