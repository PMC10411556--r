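test_that("fixed-variance Gibbs matches the closed-form BLUP", {
  pop <- tiny_pop(seed = 40, n_per_generation = 75, n_generations = 2,
                  p_snps = 300, n_qtl = 100, h2 = c(0.5, 0.5))
  ph <- pop$phenotypes
  K <- grm(pop$genotypes)
  vg <- var(ph$tbv_1); ve <- var(ph$trait_1 - ph$tbv_1)
  fit <- gblup(ph, K, trait = 1,
               n_iter = 30000, burn_in = 5000, thin = 1,
               fix_variances = list(sigma2_u = vg, sigma2_e = ve),
               seed = 1)
  # closed-form BLUP at the same variance ratio, GLS intercept
  y <- ph$trait_1
  V <- K * vg + diag(ve, nrow(K))
  Vi <- solve(V)
  mu_gls <- sum(Vi %*% y) / sum(Vi)
  u_hat <- as.numeric(vg * K %*% Vi %*% (y - mu_gls))
  expect_lt(sqrt(mean((fit$u_mean - u_hat)^2)), 0.01 * sd(y))
  expect_gt(cor(fit$u_mean, u_hat), 0.999)
})

test_that("single-trait chain recovers a known heritability", {
  pop <- tiny_pop(seed = 41, n_per_generation = 200, n_generations = 2,
                  p_snps = 400, n_qtl = 200, h2 = c(0.5, 0.5))
  fit <- gblup(pop$phenotypes, grm(pop$genotypes), trait = 1,
               n_iter = 2000, burn_in = 500, thin = 2, seed = 2)
  expect_equal(mean(fit$draws$h2), 0.5, tolerance = 0.1)
})

test_that("an overwhelming prior dominates the variance posterior", {
  pop <- tiny_pop(seed = 42, n_per_generation = 30, n_generations = 1)
  fit <- gblup(pop$phenotypes, grm(pop$genotypes), trait = 1,
               n_iter = 600, burn_in = 100, thin = 1,
               prior_df = 1e5, prior_scale = 0.8, seed = 3)
  expect_equal(mean(fit$draws$sigma2_u), 0.8, tolerance = 0.05)
  expect_equal(mean(fit$draws$sigma2_e), 0.8, tolerance = 0.05)
})

test_that("duplicated traits drive the genetic correlation toward one", {
  pop <- tiny_pop(seed = 43, n_per_generation = 60, n_generations = 2,
                  p_snps = 200, n_qtl = 80, h2 = c(0.5, 0.5))
  ph <- pop$phenotypes
  ph$trait_2 <- ph$trait_1
  fit <- mt_gblup(ph, grm(pop$genotypes), traits = c(1, 2),
                  n_iter = 1200, burn_in = 400, thin = 2, seed = 4)
  expect_gt(mean(fit$draws$r_g_12), 0.95)
})

test_that("bi-trait chain recovers heritabilities and genetic correlation", {
  pop <- sim_population(sim_config(n_per_generation = 200, n_generations = 2,
                                   p_snps = 400, n_qtl = 200,
                                   h2 = c(0.5, 0.5), genetic_corr = 0.5,
                                   residual_corr = 0.2, seed = 44))
  fit <- mt_gblup(pop$phenotypes, grm(pop$genotypes), traits = c(1, 2),
                  n_iter = 1500, burn_in = 500, thin = 2, seed = 5)
  g <- glance(fit)
  expect_equal(g$h2_1, 0.5, tolerance = 0.12)
  expect_equal(g$h2_2, 0.5, tolerance = 0.12)
  expect_equal(g$r_g_12, 0.5, tolerance = 0.15)
})

test_that("CV1 ignores and CV2 uses test-set secondary records", {
  pop <- sim_population(sim_config(n_per_generation = 60, n_generations = 3,
                                   p_snps = 150, n_qtl = 60,
                                   h2 = c(0.4, 0.6), genetic_corr = 0.7,
                                   seed = 45))
  ph <- pop$phenotypes
  split <- forward_split(ph, 0:1, 2)
  K <- grm(pop$genotypes)
  ph_perm <- ph
  in_test <- ph$id %in% split$test_ids
  set.seed(9)
  ph_perm$trait_2[in_test] <- sample(ph$trait_2[in_test])

  chain <- list(n_iter = 800, burn_in = 300, thin = 1)
  p_cv1 <- predict(mt_gblup(ph, K, test_ids = split$test_ids,
                            design = "CV1", n_iter = chain$n_iter,
                            burn_in = chain$burn_in, thin = chain$thin,
                            seed = 6))
  p_cv1_perm <- predict(mt_gblup(ph_perm, K, test_ids = split$test_ids,
                                 design = "CV1", n_iter = chain$n_iter,
                                 burn_in = chain$burn_in, thin = chain$thin,
                                 seed = 6))
  expect_equal(p_cv1_perm$.pred, p_cv1$.pred, tolerance = 1e-10)

  p_cv2 <- predict(mt_gblup(ph, K, test_ids = split$test_ids,
                            design = "CV2", n_iter = chain$n_iter,
                            burn_in = chain$burn_in, thin = chain$thin,
                            seed = 6))
  p_cv2_perm <- predict(mt_gblup(ph_perm, K, test_ids = split$test_ids,
                                 design = "CV2", n_iter = chain$n_iter,
                                 burn_in = chain$burn_in, thin = chain$thin,
                                 seed = 6))
  expect_gt(max(abs(p_cv2_perm$.pred - p_cv2$.pred)), 1e-6)
})

test_that("an identity kernel shares no information with the test set", {
  pop <- tiny_pop(seed = 46, n_per_generation = 40, n_generations = 2)
  ph <- pop$phenotypes
  split <- forward_split(ph, 0, 1)
  I_k <- diag(nrow(ph))
  rownames(I_k) <- colnames(I_k) <- ph$id
  fit <- gblup(ph, I_k, trait = 1, test_ids = split$test_ids,
               n_iter = 1500, burn_in = 500, thin = 1, seed = 7)
  pr <- predict(fit)
  y_train <- ph$trait_1[ph$id %in% split$train_ids]
  expect_lt(sd(pr$u), 0.1 * sd(y_train))
  expect_equal(mean(pr$.pred), mean(y_train), tolerance = 0.3 * sd(y_train))
})

test_that("GBLUP and a linear SVR on the same kernel broadly agree", {
  pop <- sim_population(sim_config(n_per_generation = 125, n_generations = 2,
                                   p_snps = 400, n_qtl = 200,
                                   h2 = c(0.5, 0.5), seed = 47))
  ph <- pop$phenotypes
  split <- forward_split(ph, 0, 1)
  K <- grm(pop$genotypes)
  p_gblup <- predict(gblup(ph, K, trait = 1, test_ids = split$test_ids,
                           n_iter = 2000, burn_in = 500, thin = 2, seed = 8))
  svr_lin <- qmtsvr_fit(phenotypes = ph, split = split, design = "ST",
                        kernel = K, cost = 2, epsilon = 0.05)
  p_svr <- predict(svr_lin)
  expect_gt(cor(p_gblup$.pred, p_svr$.pred[match(p_gblup$id, p_svr$id)]),
            0.95)
})

test_that("chains replay exactly from the same seed", {
  pop <- tiny_pop(seed = 48, n_per_generation = 30, n_generations = 1)
  K <- grm(pop$genotypes)
  a <- gblup(pop$phenotypes, K, n_iter = 300, burn_in = 100, thin = 1,
             seed = 10)
  b <- gblup(pop$phenotypes, K, n_iter = 300, burn_in = 100, thin = 1,
             seed = 10)
  expect_equal(a$draws, b$draws)
  expect_equal(a$u_mean, b$u_mean)
})
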