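#' Configuration for the breeding-population simulator
#'
#' Assembles and validates the parameters of [sim_population()]. Defaults
#' emulate a commercial broiler breeding setting at desk scale: a target
#' carcass trait of high heritability paired with an in-vivo indicator trait
#' of moderate heritability, weak genetic correlation and a moderate
#' environmental correlation, discrete generations with optional truncation
#' selection on the indicator trait.
#'
#' @param n_per_generation Individuals born per discrete generation.
#' @param n_generations Number of discrete generations (labelled `0, 1, ...`).
#' @param p_snps Number of biallelic SNP markers (dosage coded 0/1/2).
#' @param maf_range Range of founder allele frequencies (uniform draw).
#' @param n_qtl Number of causal loci (drawn among the SNPs).
#' @param h2 Length-`t` vector of target narrow-sense heritabilities in (0,1).
#' @param genetic_corr Genetic correlation between traits: a scalar (for
#'   `t = 2`) or a `t x t` positive-definite correlation matrix.
#' @param residual_corr Residual (environmental) correlation, same forms.
#' @param epistasis_fraction Fraction of genetic variance contributed by
#'   pairwise epistatic interactions among causal loci, in `[0, 1]`.
#' @param select_prop Proportion of candidates retained as parents each
#'   generation; `1` means random mating, smaller values apply truncation
#'   selection on a noisy phenotype of trait 1 (the trait "under selection").
#' @param prop_missing Proportion of genotype calls set missing (`NA`)
#'   uniformly at random.
#' @param reliability_range Range of simulated per-record reliabilities,
#'   stand-ins for the reliability of deregressed pseudo-phenotypes.
#' @param seed Integer seed; every run is fully reproducible from it.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_per_generation = 50, n_generations = 3, p_snps = 200)
sim_config <- function(n_per_generation = 200,
                       n_generations = 5,
                       p_snps = 1000,
                       maf_range = c(0.05, 0.5),
                       n_qtl = 300,
                       h2 = c(0.56, 0.34),
                       genetic_corr = 0.23,
                       residual_corr = 0.47,
                       epistasis_fraction = 0,
                       select_prop = 1,
                       prop_missing = 0,
                       reliability_range = c(0.5, 0.99),
                       seed = 1L) {
  t <- length(h2)
  stopifnot(n_per_generation >= 2, n_generations >= 1, p_snps >= 1,
            n_qtl >= 1, n_qtl <= p_snps,
            all(h2 > 0), all(h2 < 1),
            epistasis_fraction >= 0, epistasis_fraction <= 1,
            select_prop > 0, select_prop <= 1,
            prop_missing >= 0, prop_missing < 1)
  cfg <- list(
    n_per_generation = as.integer(n_per_generation),
    n_generations = as.integer(n_generations),
    p_snps = as.integer(p_snps),
    maf_range = maf_range,
    n_qtl = as.integer(n_qtl),
    h2 = h2,
    genetic_corr = as_corr_matrix(genetic_corr, t, "genetic_corr"),
    residual_corr = as_corr_matrix(residual_corr, t, "residual_corr"),
    epistasis_fraction = epistasis_fraction,
    select_prop = select_prop,
    prop_missing = prop_missing,
    reliability_range = reliability_range,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

# validate/expand a correlation specification into a PD t x t matrix
as_corr_matrix <- function(x, t, what) {
  if (is.matrix(x)) {
    R <- x
  } else if (length(x) == 1 && t == 2) {
    R <- matrix(c(1, x, x, 1), 2, 2)
  } else if (length(x) == 1 && t == 1) {
    R <- matrix(1, 1, 1)
  } else {
    abort(sprintf("`%s` must be a scalar (t = 2) or a %d x %d matrix", what, t, t))
  }
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-8))
    abort(sprintf("`%s` must be symmetric with unit diagonal", what))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    abort(sprintf("`%s` is not positive definite (min eigenvalue %.3g)", what, min(ev)))
  R
}

# Mendelian gamete from a 0/1/2 genotype matrix (rows = parents)
sim_gamete <- function(P) {
  het <- P == 1L
  gam <- (P == 2L) * 1L
  gam[het] <- rbinom(sum(het), 1L, 0.5)
  gam
}

#' Simulate a multi-generation genotyped population with correlated traits
#'
#' Founder genotypes are drawn per SNP from binomial(2, q) with q uniform on
#' `maf_range`; later generations arise by (optionally truncated) selection of
#' parents and Mendelian transmission, so drift and selection shape allele
#' frequencies over time. QTL effects for the `t` traits are drawn from a
#' multivariate normal with the requested genetic correlation; residuals are
#' drawn with the requested residual correlation and scaled so the realized
#' heritabilities match `h2`. True breeding values are recorded.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `genotypes` (integer matrix, individuals by
#'   SNPs, `NA` = missing, rownames = ids) and `phenotypes` (tibble with
#'   columns `id`, `generation`, `trait_*`, `rel_*`, `tbv_*`).
#' @export
#' @examples
#' pop <- sim_population(sim_config(n_per_generation = 40, n_generations = 2,
#'                                  p_snps = 100, n_qtl = 20, seed = 7))
#' dim(pop$genotypes)
#' pop$phenotypes
sim_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_gen <- config$n_generations
  n <- config$n_per_generation
  p <- config$p_snps
  t <- length(config$h2)
  N <- n * n_gen

  q <- runif(p, config$maf_range[1], config$maf_range[2])
  qtl <- sort(sample.int(p, config$n_qtl))
  B <- matrix(rnorm(config$n_qtl * t), config$n_qtl, t) %*%
    chol(config$genetic_corr)

  epi <- NULL
  if (config$epistasis_fraction > 0) {
    pairs <- matrix(sample(qtl, 2 * config$n_qtl, replace = TRUE), ncol = 2)
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    Bepi <- matrix(rnorm(nrow(pairs) * t), nrow(pairs), t) %*%
      chol(config$genetic_corr)
    epi <- list(pairs = pairs, effects = Bepi)
  }

  G <- matrix(0L, N, p)
  generation <- rep(seq_len(n_gen) - 1L, each = n)
  cur <- matrix(rbinom(n * p, 2L, rep(q, each = n)), n, p)
  G[1:n, ] <- cur
  if (n_gen > 1) {
    h2_1 <- config$h2[1]
    for (g in 2:n_gen) {
      pool <- seq_len(n)
      if (config$select_prop < 1) {
        tbv1 <- as.numeric(cur[, qtl, drop = FALSE] %*% B[, 1])
        vg <- var(tbv1)
        noise <- rnorm(n, 0, sqrt(max(vg, 1e-12) * (1 - h2_1) / h2_1))
        keep <- order(tbv1 + noise, decreasing = TRUE)
        pool <- keep[seq_len(max(2L, ceiling(n * config$select_prop)))]
      }
      dams <- sample(pool, n, replace = TRUE)
      sires <- sample(pool, n, replace = TRUE)
      cur <- sim_gamete(cur[dams, , drop = FALSE]) +
        sim_gamete(cur[sires, , drop = FALSE])
      G[(g - 1L) * n + 1:n, ] <- cur
    }
  }

  # genetic values: additive (+ optional pairwise epistasis), then scale
  g_add <- G[, qtl, drop = FALSE] %*% B
  g_tot <- g_add
  if (!is.null(epi)) {
    Z1 <- scale(G[, epi$pairs[, 1], drop = FALSE], scale = FALSE)
    Z2 <- scale(G[, epi$pairs[, 2], drop = FALSE], scale = FALSE)
    g_epi <- (Z1 * Z2) %*% epi$effects
    f <- config$epistasis_fraction
    for (k in seq_len(t)) {
      va <- var(g_add[, k]); ve <- var(g_epi[, k])
      if (ve > 0) g_epi[, k] <- g_epi[, k] * sqrt(f / (1 - f) * va / ve)
    }
    g_tot <- g_add + g_epi
  }

  vg <- apply(g_tot, 2, var)
  ve <- vg * (1 - config$h2) / config$h2
  Sigma_e <- diag(sqrt(ve), t) %*% config$residual_corr %*% diag(sqrt(ve), t)
  E <- matrix(rnorm(N * t), N, t) %*% chol(Sigma_e)
  Y <- g_tot + E

  if (config$prop_missing > 0) {
    nmiss <- round(config$prop_missing * length(G))
    G[sample.int(length(G), nmiss)] <- NA_integer_
  }

  ids <- sprintf("id_%05d", seq_len(N))
  rownames(G) <- ids
  colnames(G) <- sprintf("snp_%05d", seq_len(p))

  rel <- matrix(runif(N * t, config$reliability_range[1],
                      config$reliability_range[2]), N, t)
  phen <- tibble(id = ids, generation = generation)
  for (k in seq_len(t)) phen[[paste0("trait_", k)]] <- Y[, k]
  for (k in seq_len(t)) phen[[paste0("rel_", k)]] <- rel[, k]
  for (k in seq_len(t)) phen[[paste0("tbv_", k)]] <- g_tot[, k]

  list(genotypes = G, phenotypes = phen, config = config)
}

#' Filter SNPs on minor allele frequency and call rate
#'
#' Retains SNPs whose minor allele frequency is strictly greater than
#' `maf_min` and whose non-missing fraction is strictly greater than
#' `call_rate_min` (both computed from the data at hand). The returned matrix
#' carries a `"qc"` attribute with the counts removed per criterion.
#'
#' @param geno Integer genotype matrix (individuals x SNPs, 0/1/2, `NA`
#'   allowed).
#' @param maf_min Minor-allele-frequency threshold in `[0, 0.5)`.
#' @param call_rate_min Call-rate threshold in `(0, 1]`.
#' @return The filtered genotype matrix.
#' @export
qc_filter_snps <- function(geno, maf_min = 0.05, call_rate_min = 0.95) {
  stopifnot(is.matrix(geno), maf_min >= 0, maf_min < 0.5,
            call_rate_min > 0, call_rate_min <= 1)
  call_rate <- colMeans(!is.na(geno))
  q <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(q, 1 - q)
  maf[is.nan(maf)] <- 0
  pass_maf <- maf > maf_min
  pass_cr <- call_rate > call_rate_min
  keep <- pass_maf & pass_cr
  if (!any(keep))
    abort("all SNPs removed by QC; relax `maf_min`/`call_rate_min`")
  out <- geno[, keep, drop = FALSE]
  attr(out, "qc") <- list(
    n_removed_maf = sum(!pass_maf),
    n_removed_call_rate = sum(!pass_cr),
    n_removed = sum(!keep),
    n_retained = sum(keep)
  )
  out
}

#' Filter individuals on per-trait record reliability
#'
#' Keeps individuals whose reliability exceeds `r_min` for every trait
#' (columns `rel_*`), emulating the practice of restricting genomic analyses
#' to pseudo-phenotypes of sufficient reliability.
#'
#' @param phenotypes Phenotype tibble with `rel_*` columns.
#' @param r_min Reliability threshold.
#' @return The filtered tibble (a warning is raised if empty).
#' @export
filter_reliability <- function(phenotypes, r_min = 0.4) {
  rel_cols <- grep("^rel_", names(phenotypes), value = TRUE)
  if (length(rel_cols) == 0)
    abort("`phenotypes` has no `rel_*` columns")
  keep <- Reduce(`&`, lapply(rel_cols, function(cc) phenotypes[[cc]] > r_min))
  out <- phenotypes[keep, , drop = FALSE]
  if (nrow(out) == 0) warn("reliability filter removed every individual")
  out
}

#' Forward-in-time split by generation
#'
#' Partitions individuals into training and testing sets by their generation
#' label (forward validation: older generations train, younger generations
#' test). An optional nested inner-validation split (by generation, within the
#' training set) supports hyperparameter-tuning fitness evaluation.
#'
#' @param phenotypes Phenotype tibble with `id` and `generation` columns.
#' @param train_generations,test_generations Disjoint sets of generation
#'   labels. `test_generations` may be empty (all-train split).
#' @param inner_validation Optional generations (subset of
#'   `train_generations`) held out inside the training window for tuning.
#' @return An `mtsvr_split` list with `train_ids`, `test_ids` and, when
#'   requested, `inner_train_ids` / `inner_val_ids`.
#' @export
forward_split <- function(phenotypes, train_generations, test_generations,
                          inner_validation = NULL) {
  if (length(intersect(train_generations, test_generations)) > 0)
    abort("train and test generation sets overlap")
  gen <- phenotypes$generation
  out <- list(
    train_ids = phenotypes$id[gen %in% train_generations],
    test_ids = phenotypes$id[gen %in% test_generations],
    train_generations = train_generations,
    test_generations = test_generations
  )
  if (!is.null(inner_validation)) {
    if (!all(inner_validation %in% train_generations))
      abort("`inner_validation` must be a subset of `train_generations`")
    inner_train <- setdiff(train_generations, inner_validation)
    out$inner_train_ids <- phenotypes$id[gen %in% inner_train]
    out$inner_val_ids <- phenotypes$id[gen %in% inner_validation]
  }
  structure(out, class = "mtsvr_split")
}

#' @export
print.mtsvr_split <- function(x, ...) {
  cat("<mtsvr_split>\n")
  cat("  train:", length(x$train_ids), "ids (generations",
      paste(x$train_generations, collapse = ", "), ")\n")
  cat("  test: ", length(x$test_ids), "ids (generations",
      paste(x$test_generations, collapse = ", "), ")\n")
  if (!is.null(x$inner_val_ids))
    cat("  inner validation:", length(x$inner_val_ids), "ids\n")
  invisible(x)
}
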