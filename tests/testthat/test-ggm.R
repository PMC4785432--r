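random_spd <- function(p, n = 4 * p, seed = 1) {
  set.seed(seed)
  crossprod(matrix(rnorm(n * p), n, p)) / n
}

test_that("zero mask encodes the three constraint rules", {
  m <- c("mA", "mB"); g <- c("g1", "g2", "g3")
  db <- structure(list(targets = list(mA = "g1"), universe = g),
                  class = "target_db")
  ppi <- igraph::graph_from_data_frame(
    data.frame(a = "g1", b = "g2"), directed = FALSE,
    vertices = data.frame(name = g))
  mask <- build_zero_mask(m, g, db, ppi)
  expect_true(mask["mA", "g1"])
  expect_false(mask["mA", "g2"])            # not a target
  expect_false(mask["mA", "mB"])            # miRNA-miRNA
  expect_true(mask["g1", "g2"])
  expect_false(mask["g1", "g3"])            # not a PPI edge
  expect_equal(attr(mask, "n_free"), 2)
  expect_true(all(diag(mask)))

  empty <- build_zero_mask(m, g, NULL, NULL)
  expect_equal(attr(empty, "n_free"), 0)
  one <- build_zero_mask("mA", "g1", db, NULL)
  expect_equal(attr(one, "n_free"), 1)
  expect_error(build_zero_mask(c("x"), c("x")), "disjoint")
})

test_that("permitted-edge count equals the annotation edge count", {
  gs <- tiny_study(seed = 6)
  mids <- rownames(gs$study$mirna_matrix)[1:10]
  gids <- rownames(gs$study$gene_matrix)[1:50]
  db <- generate_target_db(mids, gids, truth = NULL, decoy_density = 0.1,
                           seed = 2)
  ppi <- generate_ppi(gids, 0.05, seed = 3)
  mask <- build_zero_mask(mids, gids, db, ppi)
  n_target_edges <- sum(vapply(db$targets[mids], length, integer(1)))
  expect_equal(attr(mask, "n_free"),
               n_target_edges + igraph::ecount(ppi))
})

test_that("unpenalized full-mask fit inverts the covariance", {
  S <- random_spd(6, seed = 2)
  fit <- fit_constrained_glasso(S, 0, tol = 1e-7)
  expect_lt(max(abs(fit$theta - solve(S))), 1e-5)
  expect_true(fit$converged)
})

test_that("structural zeros are exact and closed forms hold", {
  S <- random_spd(2, seed = 3)
  mask <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  fit <- fit_constrained_glasso(S, 0, mask)
  expect_equal(fit$theta, diag(1 / diag(S)), tolerance = 1e-8)

  # rho dominating every off-diagonal: diagonal solution 1/(S_ii + rho)
  S5 <- random_spd(5, seed = 4)
  rho <- max(abs(S5[upper.tri(S5)])) + 0.01
  fit5 <- fit_constrained_glasso(S5, rho)
  expect_equal(diag(fit5$theta), 1 / (diag(S5) + rho), tolerance = 1e-10)
  expect_true(all(abs(fit5$theta[upper.tri(fit5$theta)]) < 1e-12))

  # random masks: forbidden entries below working precision
  set.seed(5)
  for (i in 1:5) {
    p <- 6
    S6 <- random_spd(p, seed = 10 + i)
    msk <- matrix(runif(p * p) < 0.5, p, p)
    msk <- msk | t(msk); diag(msk) <- TRUE
    f <- fit_constrained_glasso(S6, 0.02, msk)
    expect_lt(max(abs(f$theta[!msk])), 1e-8)
    expect_gt(min(eigen(f$theta, symmetric = TRUE)$values), 0)
  }
})

test_that("fit matches a generic constrained solver on 3x3 problems", {
  for (i in 1:6) {
    S <- random_spd(3, seed = 20 + i)
    rho <- c(0.01, 0.05, 0.1)[(i %% 3) + 1]
    mask <- matrix(TRUE, 3, 3); mask[1, 3] <- mask[3, 1] <- FALSE
    fit <- fit_constrained_glasso(S, rho, mask, tol = 1e-7)
    obj <- glasso_objective(fit$theta, S, rho)
    obj_nm <- nm_solve_3x3(S, rho, seed = i)
    expect_lt(abs(obj - obj_nm), 1e-6)
  }
})

test_that("regression view reproduces conditional-Gaussian coefficients", {
  # bivariate unit-variance precision for correlation r -> slope r
  r <- 0.6
  theta <- solve(matrix(c(1, r, r, 1), 2, 2))
  reg <- precision_to_regression(theta, 2)
  expect_equal(unname(reg$coef), r, tolerance = 1e-12)

  # structurally zero precision entry -> zero coefficient
  th0 <- diag(c(2, 3, 4)); th0[1, 2] <- th0[2, 1] <- -0.5
  reg0 <- precision_to_regression(th0, 3)
  expect_equal(unname(reg0$coef), c(0, 0))

  # random SPD: matches the covariance-side conditional mean
  set.seed(6)
  for (i in 1:5) {
    A <- random_spd(4, seed = 30 + i) + diag(4) * 0.5
    for (j in 1:4) {
      reg <- precision_to_regression(A, j)
      expect_equal(unname(reg$coef), unname(oracle_conditional_coef(A, j)),
                   tolerance = 1e-8)
    }
  }
})

test_that("rho selection minimizes CV MSE with sparse tie-breaking", {
  expect_equal(select_rho(matrix(rnorm(40), 10, 4),
                          matrix(TRUE, 4, 4), grid = 0.3,
                          mirna_ids = 1)$rho, 0.3)
  set.seed(7)
  # pure noise: nothing predictable, the largest penalty wins when the
  # criterion is averaged over several miRNA nodes
  noise <- matrix(rnorm(20 * 8), 20, 8,
                  dimnames = list(NULL, c(paste0("m", 1:4),
                                          paste0("g", 1:4))))
  msk <- matrix(TRUE, 8, 8)
  sel <- select_rho(noise, msk, grid = c(0.01, 0.1, 1, 10),
                    mirna_ids = paste0("m", 1:4))
  expect_equal(sel$rho, 10)
  # strong linear structure: small rho, much better CV MSE
  z <- rnorm(30)
  strong <- cbind(m = z + rnorm(30, 0, 0.05),
                  g1 = z + rnorm(30, 0, 0.05),
                  g2 = z + rnorm(30, 0, 0.05))
  sel2 <- select_rho(strong, matrix(TRUE, 3, 3),
                     grid = c(0.001, 0.01, 1, 10), mirna_ids = "m")
  expect_lte(sel2$rho, 0.01)
  expect_lt(min(sel2$cv_mse), 0.1 * sel2$cv_mse[["10"]])
})

test_that("leave-one-out prediction spans the predictable-to-null range", {
  set.seed(8)
  n <- 20
  z <- rnorm(n)
  dat <- cbind(m = z, g1 = z, g2 = rnorm(n))
  msk <- matrix(TRUE, 3, 3)
  cv <- cv_predict_mirna(dat, msk, 1e-4, "m")
  expect_gt(cv$r2, 0.99)
  expect_lt(cv$mse, 1e-3)

  # an independent miRNA carries no predictive signal: across repeated
  # draws the typical r2 stays near zero and the MSE near its variance
  ni <- 200
  r2s <- mse_ratio <- numeric(8)
  for (s in 1:8) {
    set.seed(400 + s)
    ind <- matrix(rnorm(ni * 5), ni, 5,
                  dimnames = list(NULL, c("m", paste0("g", 1:4))))
    cvi <- cv_predict_mirna(ind, matrix(TRUE, 5, 5), 0.02, "m")
    r2s[s] <- cvi$r2
    mse_ratio[s] <- cvi$mse / var(ind[, "m"])
  }
  expect_lt(median(r2s), 0.1)
  expect_true(all(r2s < 0.6))
  expect_true(all(mse_ratio > 0.7 & mse_ratio < 1.5))

  # no permitted neighbours: mean predictor, r2 defined as 0
  ind3 <- cbind(m = rnorm(n), g1 = rnorm(n), g2 = rnorm(n))
  none <- msk; none[1, 2:3] <- none[2:3, 1] <- FALSE
  cvn <- cv_predict_mirna(ind3, none, 0.03, "m")
  expect_equal(cvn$r2, 0)
  loo_mean <- vapply(seq_len(n), function(i) mean(ind3[-i, "m"]), numeric(1))
  expect_equal(cvn$mse, mean((ind3[, "m"] - loo_mean)^2), tolerance = 1e-12)
})

test_that("permutation validation obeys its proportion definition", {
  set.seed(9)
  npool <- 80; ns <- 14
  gids <- sprintf("g%03d", 1:npool)
  ge <- matrix(rnorm(npool * ns), npool, ns,
               dimnames = list(gids, paste0("s", 1:ns)))
  db <- structure(list(targets = setNames(list(gids), "m1"),
                       universe = gids), class = "target_db")
  ppi <- generate_ppi(gids, 0, seed = 1)
  # the first candidate gene tracks the miRNA almost exactly; random
  # gene sets are pure noise
  mir <- setNames(ge[1, ] + rnorm(ns, 0, 1e-3), colnames(ge))
  pv <- permutation_validate(ge, mir, "m1", gids[1:3], db, ppi,
                             rho = 1e-4, n_rep = 50, seed = 2)
  expect_equal(pv$p_mse, 0)
  expect_equal(pv$p_r2, 0)
  expect_error(
    permutation_validate(ge, mir, "m1", gids[1:3], db, ppi, 0.03,
                         n_rep = 0), "positive")
  expect_error(
    permutation_validate(ge[1:3, ], mir, "m1", gids[1:3], db, ppi, 0.03,
                         n_rep = 10), "larger")
})

test_that("results are invariant to sample order", {
  set.seed(10)
  dat <- matrix(rnorm(15 * 4), 15, 4,
                dimnames = list(NULL, c("m", paste0("g", 1:3))))
  msk <- matrix(TRUE, 4, 4)
  a <- cv_predict_mirna(dat, msk, 0.05, "m")
  perm <- sample(15)
  b <- cv_predict_mirna(dat[perm, ], msk, 0.05, "m")
  expect_equal(sort(a$predicted), sort(b$predicted), tolerance = 1e-10)
  expect_equal(a$mse, b$mse, tolerance = 1e-10)
})
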