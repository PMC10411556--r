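#' Leading principal components of a genomic relationship matrix
#'
#' Returns the first `n` eigenvectors of `G` scaled by the square roots of
#' their eigenvalues (principal-component scores), used as covariates to
#' absorb population structure in per-SNP regressions. Signs are fixed
#' deterministically (the largest-magnitude loading of each component is made
#' positive).
#'
#' @param G Genomic relationship matrix from [grm()].
#' @param n Number of components, at most `N - 1`.
#' @return An `N x n` score matrix.
#' @export
genomic_pcs <- function(G, n) {
  N <- nrow(G)
  if (n > N - 1) abort(sprintf("`n` must be <= N - 1 = %d", N - 1))
  eg <- eigen(G, symmetric = TRUE)
  vals <- pmax(eg$values[seq_len(n)], 0)
  scores <- eg$vectors[, seq_len(n), drop = FALSE] %*% diag(sqrt(vals), n)
  for (j in seq_len(n)) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(G)
  scores
}

#' Per-SNP multivariate regression effects with genomic PC adjustment
#'
#' For each SNP independently, fits the `t` responses by least squares on
#' an intercept, the SNP dosage and the leading genomic principal components
#' (population-structure adjustment), and records the dosage coefficient per
#' trait (allele-substitution scale). With a shared design, the multivariate
#' least-squares point estimates coincide with equation-by-equation OLS, which
#' is computed efficiently by first residualizing responses and dosages on
#' the non-SNP covariates (Frisch–Waugh). SNPs that are degenerate after
#' residualization (e.g. monomorphic) get a zero effect so locus indexing
#' stays aligned with the genotype matrix.
#'
#' @param geno Genotype matrix of the training individuals.
#' @param Y `N x t` numeric matrix (or data frame) of responses, no missing
#'   values among the analyzed rows.
#' @param pcs Optional precomputed PC score matrix; when `NULL`, the first
#'   `n_pcs` components of [grm()] on `geno` are used.
#' @param n_pcs Number of genomic PCs, default `min(30, N - 2)`.
#' @return An `mtsvr_snp_effects` list: `deltas` (`p x t`), `allele_freqs`
#'   (length `p`), `n_pcs_used`.
#' @export
snp_effects <- function(geno, Y, pcs = NULL, n_pcs = NULL) {
  Y <- as.matrix(Y)
  if (anyNA(Y)) abort("`Y` has missing responses; subset to complete records")
  N <- nrow(geno)
  stopifnot(nrow(Y) == N)
  X <- impute_genotypes(geno)
  if (is.null(pcs)) {
    n_pcs <- n_pcs %||% min(30L, N - 2L)
    pcs <- if (n_pcs > 0) genomic_pcs(grm(geno), n_pcs) else NULL
  }
  covar <- cbind(rep(1, N), pcs)
  qr_c <- qr(covar)
  Y_res <- qr.resid(qr_c, Y)
  X_res <- qr.resid(qr_c, X)

  ss <- colSums(X_res^2)
  degenerate <- ss < 1e-10
  ss[degenerate] <- 1
  deltas <- crossprod(X_res, Y_res) / ss
  if (any(degenerate)) {
    deltas[degenerate, ] <- 0
    warn(sprintf("%d SNP(s) degenerate after covariate adjustment; effects set to 0",
                 sum(degenerate)))
  }
  q <- colMeans(geno, na.rm = TRUE) / 2
  structure(list(deltas = deltas, allele_freqs = q,
                 n_pcs_used = if (is.null(pcs)) 0L else ncol(pcs),
                 snp_ids = colnames(geno)),
            class = "mtsvr_snp_effects")
}

#' Normalized locus (co)variance weights for a trait pair
#'
#' Computes, per locus, the raw (co)variance contribution
#' \eqn{|2 q_l (1 - q_l) \delta_{lk} \delta_{lk'}|} and normalizes by its
#' maximum over loci, so weights range in `[0, 1]` with the maximum exactly 1
#' (variance when `k = k'`, absolute covariance otherwise). With `t` traits,
#' `t(t+1)/2` distinct weight vectors exist across pairs; weights are
#' symmetric in the pair and invariant to rescaling a trait's effects by a
#' positive constant.
#'
#' @param effects An [snp_effects()] object.
#' @param k,kp Trait indices of the pair (`k == kp` for a single trait).
#' @return A named numeric weight vector with attributes `pair` and `raw`.
#' @export
locus_weights <- function(effects, k, kp = k) {
  stopifnot(inherits(effects, "mtsvr_snp_effects"))
  q <- effects$allele_freqs
  raw <- abs(2 * q * (1 - q) * effects$deltas[, k] * effects$deltas[, kp])
  mx <- max(raw)
  if (mx <= 0)
    abort(sprintf("all locus (co)variances are zero for pair (%d,%d); weighted kernel undefined",
                  k, kp))
  w <- raw / mx
  names(w) <- effects$snp_ids
  attr(w, "pair") <- c(k, kp)
  attr(w, "raw") <- raw
  w
}

#' All pairwise locus-weight vectors
#'
#' @param effects An [snp_effects()] object.
#' @return A list of [locus_weights()] vectors keyed `"k_k'"`, one per
#'   unordered trait pair (`t(t+1)/2` entries).
#' @export
pair_weights <- function(effects) {
  t <- ncol(effects$deltas)
  out <- list()
  for (k in seq_len(t)) for (kp in k:t)
    out[[pair_key(k, kp)]] <- locus_weights(effects, k, kp)
  out
}

#' @export
#' @method tidy mtsvr_snp_effects
tidy.mtsvr_snp_effects <- function(x, ...) {
  t <- ncol(x$deltas)
  out <- tibble(snp_id = x$snp_ids, allele_freq = x$allele_freqs)
  for (k in seq_len(t)) out[[paste0("delta_", k)]] <- x$deltas[, k]
  out
}
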