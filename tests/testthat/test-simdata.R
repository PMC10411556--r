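test_that("population bookkeeping: sizes, labels, codes, reproducibility", {
  cfg <- sim_config(n_per_generation = 100, n_generations = 5,
                    p_snps = 150, n_qtl = 50, seed = 11)
  pop <- sim_population(cfg)
  expect_equal(nrow(pop$genotypes), 500)
  expect_equal(sort(unique(pop$phenotypes$generation)), 0:4)
  expect_equal(as.vector(table(pop$phenotypes$generation)), rep(100, 5))
  expect_true(all(pop$genotypes %in% 0:2))
  expect_equal(anyDuplicated(pop$phenotypes$id), 0)
  pop2 <- sim_population(cfg)
  expect_identical(pop$genotypes, pop2$genotypes)
  expect_equal(pop$phenotypes, pop2$phenotypes)
})

test_that("uncorrelated traits give near-zero breeding-value correlation", {
  # relatedness across generations inflates the sampling noise of a single
  # realization, so average the realized correlation over a few seeds
  r <- vapply(1:3, function(s) {
    pop <- sim_population(sim_config(n_per_generation = 400,
                                     n_generations = 5,
                                     p_snps = 300, n_qtl = 200,
                                     h2 = c(0.5, 0.5), genetic_corr = 0,
                                     residual_corr = 0, seed = s))
    cor(pop$phenotypes$tbv_1, pop$phenotypes$tbv_2)
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.1)
})

test_that("realized heritabilities and genetic correlation track targets", {
  h2_target <- c(0.56, 0.34)
  rg_target <- 0.23
  h2_hat <- matrix(NA_real_, 3, 2)
  rg_hat <- numeric(3)
  for (s in 1:3) {
    pop <- sim_population(sim_config(n_per_generation = 400,
                                     n_generations = 5, p_snps = 300,
                                     n_qtl = 200, h2 = h2_target,
                                     genetic_corr = rg_target, seed = s))
    ph <- pop$phenotypes
    h2_hat[s, ] <- c(var(ph$tbv_1) / var(ph$trait_1),
                     var(ph$tbv_2) / var(ph$trait_2))
    rg_hat[s] <- cor(ph$tbv_1, ph$tbv_2)
  }
  expect_true(all(abs(t(h2_hat) - h2_target) < 0.05))
  expect_lt(abs(mean(rg_hat) - rg_target), 0.1)
})

test_that("truncation selection on trait 1 moves its breeding values", {
  pop <- sim_population(sim_config(n_per_generation = 200, n_generations = 5,
                                   p_snps = 200, n_qtl = 100,
                                   select_prop = 0.2, seed = 2))
  ph <- pop$phenotypes
  first <- mean(ph$tbv_1[ph$generation == 0])
  last <- mean(ph$tbv_1[ph$generation == 4])
  expect_gt(last, first)
})

test_that("invalid correlation matrices are rejected", {
  bad <- matrix(c(1, 1.2, 1.2, 1), 2, 2)
  expect_error(sim_config(genetic_corr = bad), "positive definite")
  asym <- matrix(c(1, 0.2, 0.4, 1), 2, 2)
  expect_error(sim_config(genetic_corr = asym), "symmetric")
})

test_that("SNP QC matches small worked cases", {
  # 20 individuals; column MAFs 0.02..., engineered via fixed dosages
  G <- cbind(snp_a = c(rep(0L, 19), 1L),           # maf = 1/40 = 0.025
             snp_b = c(rep(0L, 16), rep(1L, 4)),   # maf = 0.1
             snp_c = rep(1L, 20))                  # maf = 0.5
  out <- qc_filter_snps(G, maf_min = 0.05, call_rate_min = 0.95)
  expect_equal(colnames(out), c("snp_b", "snp_c"))
  expect_equal(attr(out, "qc")$n_removed_maf, 1)

  Gm <- G
  Gm[1:2, 2] <- NA # 10% missing in snp_b
  out2 <- qc_filter_snps(Gm, maf_min = 0, call_rate_min = 0.95)
  expect_false("snp_b" %in% colnames(out2))

  expect_error(qc_filter_snps(G, maf_min = 0.49, call_rate_min = 1),
               "all SNPs removed")
})

test_that("SNP QC equals a brute-force per-column loop and is idempotent", {
  set.seed(9)
  G <- matrix(rbinom(100 * 200, 2, runif(200, 0.01, 0.5)),
              100, 200, byrow = TRUE)
  G[sample(length(G), 500)] <- NA
  colnames(G) <- sprintf("s%03d", 1:200)
  out <- qc_filter_snps(G, 0.05, 0.95)
  keep_bf <- vapply(seq_len(ncol(G)), function(j) {
    x <- G[, j]
    cr <- mean(!is.na(x))
    q <- mean(x, na.rm = TRUE) / 2
    min(q, 1 - q) > 0.05 && cr > 0.95
  }, logical(1))
  expect_equal(colnames(out), colnames(G)[keep_bf])
  twice <- qc_filter_snps(out, 0.05, 0.95)
  expect_equal(unname(twice), unname(out), ignore_attr = TRUE)
  expect_equal(ncol(twice), ncol(out))
})

test_that("reliability filter keeps only individuals passing every trait", {
  ph <- tibble::tibble(id = c("a", "b", "c"), generation = 0L,
                       trait_1 = 1:3, trait_2 = 1:3,
                       rel_1 = c(0.5, 1, 0.41), rel_2 = c(0.3, 1, 0.45))
  out <- filter_reliability(ph, 0.4)
  expect_equal(out$id, c("b", "c")) # "a" fails trait 2 only but is removed

  all_one <- dplyr::mutate(ph, rel_1 = 1, rel_2 = 1)
  expect_equal(filter_reliability(all_one, 0.4), all_one)

  set.seed(4)
  big <- tibble::tibble(id = sprintf("i%02d", 1:50), generation = 0L,
                        trait_1 = rnorm(50),
                        rel_1 = runif(50), rel_2 = runif(50))
  out2 <- filter_reliability(big, 0.4)
  expect_equal(nrow(out2), sum(pmin(big$rel_1, big$rel_2) > 0.4))

  expect_warning(filter_reliability(big, 0.999), "removed every")
})

test_that("forward split partitions individuals and supports nesting", {
  pop <- tiny_pop(seed = 3, n_generations = 5)
  ph <- pop$phenotypes
  sp <- forward_split(ph, train_generations = 0:2, test_generations = 3:4)
  expect_equal(length(sp$train_ids) + length(sp$test_ids), nrow(ph))
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)

  all_train <- forward_split(ph, 0:4, integer(0))
  expect_equal(length(all_train$train_ids), nrow(ph))
  expect_length(all_train$test_ids, 0)

  nested <- forward_split(ph, 0:3, 4, inner_validation = 3)
  expect_setequal(c(nested$inner_train_ids, nested$inner_val_ids),
                  nested$train_ids)
  expect_equal(sort(unique(ph$generation[match(nested$inner_val_ids, ph$id)])), 3)

  expect_error(forward_split(ph, 0:3, 3:4), "overlap")
  expect_error(forward_split(ph, 0:2, 4, inner_validation = 3), "subset")
})

test_that("reliability filtering and splitting commute on id identity", {
  pop <- tiny_pop(seed = 8)
  ph <- pop$phenotypes
  a <- forward_split(filter_reliability(ph, 0.6), 0:1, 2)
  b_full <- forward_split(ph, 0:1, 2)
  keep <- filter_reliability(ph, 0.6)$id
  expect_setequal(a$train_ids, intersect(b_full$train_ids, keep))
  expect_setequal(a$test_ids, intersect(b_full$test_ids, keep))
})

test_that("missing genotypes are injected at the configured rate", {
  pop <- sim_population(sim_config(n_per_generation = 100, n_generations = 2,
                                   p_snps = 200, n_qtl = 50,
                                   prop_missing = 0.05, seed = 6))
  expect_equal(mean(is.na(pop$genotypes)), 0.05, tolerance = 0.01)
})
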