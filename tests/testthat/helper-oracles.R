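# Independent oracles used to freeze expected values. Each is a brute-force
# or closed-form recomputation, deliberately written along a different path
# than the package implementation it checks.

# upper-tail hypergeometric P(X >= k) by exhaustive enumeration of draws
enum_hyper <- function(N, K, n, k) {
  if (k <= 0) return(1)
  if (n == 0) return(0)
  draws <- combn(N, n)
  succ <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% succ) >= k))
}

# one-sided ("first group smaller") rank-sum p by enumerating all rank
# assignments
enum_rank <- function(x, y) {
  nx <- length(x); ny <- length(y)
  w_obs <- sum(rank(c(x, y))[seq_len(nx)])
  pos <- combn(nx + ny, nx)
  w_all <- apply(pos, 2, sum)
  mean(w_all <= w_obs)
}

# brute-force Benjamini-Hochberg step-up from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  adj <- numeric(m)
  cur <- 1
  for (i in m:1) {
    cur <- min(cur, m * po[i] / i)
    adj[i] <- cur
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# maximum single-hairpin pairing by top-down memoized recursion
oracle_hairpin_stem <- function(sequence) {
  ch <- strsplit(chartr("Tt", "UU", toupper(sequence)), "")[[1]]
  ok <- function(a, b) paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  n <- length(ch)
  memo <- matrix(NA_integer_, n, n)
  rec <- function(i, j) {
    if (j - i <= 3L) return(0L)
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- max(rec(i + 1L, j), rec(i, j - 1L),
             if (ok(ch[i], ch[j])) rec(i + 1L, j - 1L) + 1L else 0L)
    memo[i, j] <<- v
    v
  }
  rec(1L, n)
}

# per-node graph statistics straight from the adjacency matrix
oracle_topology <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  cc <- vapply(seq_len(n), function(v) {
    k <- deg[v]
    if (k < 2) return(0)
    nb <- which(adj[v, ] == 1)
    2 * sum(adj[nb, nb]) / 2 / (k * (k - 1))
  }, numeric(1))
  list(deg = deg, mean_cc = mean(cc),
       density = sum(adj) / 2 / (n * (n - 1) / 2),
       centralization = if (n > 2) sum(max(deg) - deg) / ((n - 1) * (n - 2)) else 0,
       heterogeneity = if (mean(deg) > 0)
         sqrt(mean((deg - mean(deg))^2)) / mean(deg) else 0)
}

# regression coefficients of variable j on the rest from the covariance side
oracle_conditional_coef <- function(theta, j) {
  Sigma <- solve(theta)
  drop(solve(Sigma[-j, -j], Sigma[-j, j]))
}

# small synthetic study shared by several tests
tiny_study <- function(seed = 1, ...) {
  cfg <- study_config(n_genes = 300, n_mirnas = 30, seed = seed, ...)
  generate_study(cfg)
}

# generic constrained-optimization solver for the penalized GGM objective:
# Nelder-Mead over the free entries of Theta (diagonal on log scale),
# restarted, for 3x3 problems with one forbidden edge (1,3)
nm_solve_3x3 <- function(S, rho, n_starts = 4, seed = 1) {
  set.seed(seed)
  par2theta <- function(p) {
    th <- matrix(0, 3, 3)
    diag(th) <- exp(p[1:3])
    th[1, 2] <- th[2, 1] <- p[4]
    th[2, 3] <- th[3, 2] <- p[5]
    th
  }
  f <- function(p) -glasso_objective(par2theta(p), S, rho)
  best <- Inf
  for (s in seq_len(n_starts)) {
    p0 <- c(log(1 / diag(S)) + rnorm(3, 0, 0.1), rnorm(2, 0, 0.1))
    o <- optim(p0, f, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-14))
    o <- optim(o$par, f, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  -best
}
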