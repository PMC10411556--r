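make_split_pop <- function(seed = 1, n_per_generation = 50,
                           n_generations = 3, ...) {
  pop <- tiny_pop(seed = seed, n_per_generation = n_per_generation,
                  n_generations = n_generations, ...)
  split <- forward_split(pop$phenotypes,
                         seq_len(n_generations - 1) - 1,
                         n_generations - 1)
  list(pop = pop, split = split)
}

test_that("stacked row counts follow the validation design", {
  x <- make_split_pop(seed = 1, n_per_generation = 50, n_generations = 3)
  # 100 train individuals, 50 test
  st <- stack_traits(x$pop$phenotypes, x$split, 1, "ST")
  expect_equal(sum(st$rows$role == "train"), 100)
  expect_equal(sum(st$rows$role == "predict"), 50)

  cv1 <- stack_traits(x$pop$phenotypes, x$split, 1, "CV1")
  expect_equal(sum(cv1$rows$role == "train"), 200)
  expect_equal(sum(cv1$rows$role == "predict"), 50)

  cv2 <- stack_traits(x$pop$phenotypes, x$split, 1, "CV2")
  expect_equal(sum(cv2$rows$role == "train"), 250)
  expect_equal(sum(cv2$rows$role == "predict"), 50)

  # CV2 = CV1 + the secondary-trait rows of test individuals
  extra <- dplyr::anti_join(cv2$rows, cv1$rows,
                            by = c("id", "trait", "role"))
  expect_true(all(extra$trait == 2))
  expect_setequal(extra$id, x$split$test_ids)
})

test_that("per-trait standardization uses training rows and round-trips", {
  x <- make_split_pop(seed = 2)
  cv1 <- stack_traits(x$pop$phenotypes, x$split, 1, "CV1")
  tr <- cv1$rows[cv1$rows$role == "train", ]
  for (k in 1:2) {
    sub <- tr[tr$trait == k, ]
    std <- cv1$standardizers[cv1$standardizers$trait == k, ]
    expect_equal(std$mean, mean(sub$y))
    expect_equal(std$sd, sd(sub$y))
    expect_equal(sub$y_star * std$sd + std$mean, sub$y, tolerance = 1e-12)
  }
})

test_that("kernel assembly reduces, is symmetric and hand-indexes correctly", {
  x <- make_split_pop(seed = 3, n_per_generation = 4, n_generations = 2,
                      p_snps = 40, n_qtl = 10)
  G <- impute_genotypes(x$pop$genotypes)
  d <- sq_edm(G)
  d$ids <- rownames(G)

  st <- stack_traits(x$pop$phenotypes, x$split, 1, "ST")
  q1 <- mt_kernel(d, matrix(1.2, 1, 1))
  m1 <- assemble_q(q1, st)
  K <- rbf_kernel(d, 1.2)
  tr_ids <- st$rows$id[st$rows$role == "train"]
  expect_equal(unname(m1$K_train), unname(K[tr_ids, tr_ids]))

  theta <- matrix(c(1.5, 2, 2, 3), 2, 2)
  rho <- matrix(c(1, 0.2, 0.2, 1), 2, 2)
  q2 <- mt_kernel(d, theta, rho)
  cv2 <- stack_traits(x$pop$phenotypes, x$split, 1, "CV2")
  m2 <- assemble_q(q2, cv2)
  expect_equal(m2$K_train, t(m2$K_train))
  expect_equal(unname(diag(m2$K_train)),
               rep(1, nrow(m2$K_train)))

  tr <- cv2$rows[cv2$rows$role == "train", ]
  pr <- cv2$rows[cv2$rows$role == "predict", ]
  for (a in seq_len(nrow(pr))) for (b in seq_len(nrow(tr))) {
    i <- match(pr$id[a], d$ids); j <- match(tr$id[b], d$ids)
    k <- pr$trait[a]; kp <- tr$trait[b]
    expected <- rho[k, kp] * exp(-theta[k, kp] * d$values[i, j] / d$scale)
    expect_equal(m2$K_cross[a, b], expected)
  }
})

test_that("single-trait path is identical to a manual SVR on the RBF kernel", {
  x <- make_split_pop(seed = 4)
  fit <- qmtsvr_fit(x$pop$genotypes, x$pop$phenotypes, x$split,
                    target_trait = 1, design = "ST", theta = 1.4,
                    cost = 2, epsilon = 0.05)
  # manual replication of the pipeline
  d <- sq_edm(impute_genotypes(x$pop$genotypes))
  d$ids <- rownames(x$pop$genotypes)
  Q <- stabilize_psd(mt_kernel(d, matrix(1.4, 1, 1)), 1e-8)
  st <- stack_traits(x$pop$phenotypes, x$split, 1, "ST")
  mats <- assemble_q(Q, st)
  manual <- svr_fit(mats$K_train, st$rows$y_star[st$rows$role == "train"],
                    cost = 2, epsilon = 0.05)
  expect_identical(fit$svr$beta, manual$beta)
  expect_identical(fit$svr$b0, manual$b0)
})

test_that("uniform locus weights reproduce the unweighted fit exactly", {
  x <- make_split_pop(seed = 5)
  p <- ncol(x$pop$genotypes)
  ones <- setNames(rep(list(rep(1, p)), 3), c("1_1", "1_2", "2_2"))
  theta <- matrix(c(1, 2, 2, 1.5), 2, 2)
  rho <- matrix(c(1, 0.2, 0.2, 1), 2, 2)
  base_fit <- qmtsvr_fit(x$pop$genotypes, x$pop$phenotypes, x$split,
                         design = "CV2", theta = theta, rho = rho,
                         cost = 1, epsilon = 0.05)
  w_fit <- qmtsvr_fit(x$pop$genotypes, x$pop$phenotypes, x$split,
                      design = "CV2", theta = theta, rho = rho,
                      cost = 1, epsilon = 0.05, weights = ones)
  expect_equal(predict(w_fit)$.pred, predict(base_fit)$.pred,
               tolerance = 1e-12)
  expect_true(w_fit$weighted)
})

test_that("CV1 predictions ignore test phenotypes entirely (no leakage)", {
  x <- make_split_pop(seed = 6)
  ph <- x$pop$phenotypes
  fit <- qmtsvr_fit(x$pop$genotypes, ph, x$split, design = "CV1",
                    theta = matrix(c(1, 2, 2, 1.5), 2, 2),
                    rho = matrix(c(1, 0.2, 0.2, 1), 2, 2),
                    cost = 1, epsilon = 0.05)
  ph_perturbed <- ph
  in_test <- ph$id %in% x$split$test_ids
  ph_perturbed$trait_1[in_test] <- ph$trait_1[in_test] + 100
  ph_perturbed$trait_2[in_test] <- ph$trait_2[in_test] * -3
  fit2 <- qmtsvr_fit(x$pop$genotypes, ph_perturbed, x$split, design = "CV1",
                     theta = matrix(c(1, 2, 2, 1.5), 2, 2),
                     rho = matrix(c(1, 0.2, 0.2, 1), 2, 2),
                     cost = 1, epsilon = 0.05)
  expect_equal(predict(fit2)$.pred, predict(fit)$.pred, tolerance = 1e-12)
})

test_that("a tube wider than the data returns a constant prediction", {
  x <- make_split_pop(seed = 7)
  fit <- qmtsvr_fit(x$pop$genotypes, x$pop$phenotypes, x$split,
                    design = "ST", theta = 1, cost = 1, epsilon = 10)
  expect_length(fit$svr$sv, 0)
  pr <- predict(fit)
  std <- fit$stack$standardizers
  expect_equal(pr$.pred,
               rep(std$mean + std$sd * fit$svr$b0, nrow(pr)))
})

test_that("test-individual ordering does not change their predictions", {
  x <- make_split_pop(seed = 8)
  theta <- matrix(c(1, 2, 2, 1.5), 2, 2)
  rho <- matrix(c(1, 0.2, 0.2, 1), 2, 2)
  f1 <- qmtsvr_fit(x$pop$genotypes, x$pop$phenotypes, x$split,
                   design = "CV2", theta = theta, rho = rho,
                   cost = 1, epsilon = 0.05)
  split_shuffled <- x$split
  set.seed(1)
  split_shuffled$test_ids <- sample(split_shuffled$test_ids)
  f2 <- qmtsvr_fit(x$pop$genotypes, x$pop$phenotypes, split_shuffled,
                   design = "CV2", theta = theta, rho = rho,
                   cost = 1, epsilon = 0.05)
  p1 <- predict(f1); p2 <- predict(f2)
  expect_equal(p2$.pred[match(p1$id, p2$id)], p1$.pred, tolerance = 1e-10)
})

test_that("a linear SVR runs on a precomputed genomic relationship kernel", {
  x <- make_split_pop(seed = 9)
  G <- grm(x$pop$genotypes)
  fit <- qmtsvr_fit(phenotypes = x$pop$phenotypes, split = x$split,
                    design = "ST", kernel = G, cost = 2, epsilon = 0.05)
  pr <- predict(fit)
  expect_equal(nrow(pr), length(x$split$test_ids))
  expect_true(all(is.finite(pr$.pred)))
})

test_that("design preconditions raise informative errors", {
  x <- make_split_pop(seed = 10)
  ph <- x$pop$phenotypes
  ph$trait_2[ph$id %in% x$split$test_ids][1] <- NA
  expect_error(stack_traits(ph, x$split, 1, "CV2"),
               "CV2 requires the secondary trait")
  ph2 <- x$pop$phenotypes
  ph2$trait_1[ph2$id %in% x$split$train_ids][1] <- NA
  expect_error(stack_traits(ph2, x$split, 1, "CV1"), "target trait")
})
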