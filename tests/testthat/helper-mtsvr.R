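# Shared fixtures and independent oracles for the test suite.

# small simulated population, cheap enough for most unit tests
tiny_pop <- function(seed = 1, n_per_generation = 40, n_generations = 3,
                     p_snps = 120, n_qtl = 60, ...) {
  sim_population(sim_config(n_per_generation = n_per_generation,
                            n_generations = n_generations,
                            p_snps = p_snps, n_qtl = n_qtl,
                            seed = seed, ...))
}

# random PSD kernel with well-separated spectrum (unique dual solutions)
random_kernel <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * 2 * n), 2 * n, n)
  crossprod(A) / (2 * n) + 0.5 * diag(n)
}

# Generic QP oracle for the epsilon-SVR dual, independent of the SMO path:
# augmented-Lagrangian box-constrained minimization (L-BFGS-B) over the
# 2n-variable form z = (alpha, alpha*) of
#   min 1/2 beta' K beta + sum_i p_i z_i ,  p = (eps - y, eps + y),
#   s.t. sum(beta) = 0, 0 <= z <= C,  beta = alpha - alpha*.
svr_qp_oracle <- function(K, y, C, eps, outer_iter = 80, feas_tol = 1e-12) {
  n <- length(y)
  p <- c(eps - y, eps + y)
  idx_a <- seq_len(n)
  idx_b <- n + idx_a
  lam <- 0
  mu <- 10
  z <- rep(0, 2 * n)
  fn <- function(z) {
    beta <- z[idx_a] - z[idx_b]
    g <- sum(beta)
    0.5 * sum(beta * (K %*% beta)) + sum(p * z) + lam * g + 0.5 * mu * g^2
  }
  gr <- function(z) {
    beta <- z[idx_a] - z[idx_b]
    Kb <- as.numeric(K %*% beta)
    g <- sum(beta)
    c(Kb + p[idx_a] + lam + mu * g,
      -Kb + p[idx_b] - lam - mu * g)
  }
  g_prev <- Inf
  for (it in seq_len(outer_iter)) {
    res <- stats::optim(z, fn, gr, method = "L-BFGS-B",
                        lower = 0, upper = C,
                        control = list(maxit = 2000, factr = 10))
    z <- res$par
    g <- sum(z[idx_a] - z[idx_b])
    lam <- lam + mu * g
    if (abs(g) < feas_tol && it > 2) break
    if (abs(g) > 0.25 * abs(g_prev)) mu <- mu * 5
    g_prev <- g
  }
  beta <- z[idx_a] - z[idx_b]
  list(beta = beta,
       z = z,
       objective = -0.5 * sum(beta * (K %*% beta)) - eps * sum(z) +
         sum(y * beta),
       feasibility = sum(beta))
}
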