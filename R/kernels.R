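#' Mean-impute missing genotype calls
#'
#' Replaces `NA` dosages by the per-SNP mean of the observed calls (the
#' expectation under the observed allele frequency). Distance and relationship
#' computations require a complete matrix.
#'
#' @param geno Genotype matrix (0/1/2 with `NA`).
#' @return A numeric matrix without missing values.
#' @export
impute_genotypes <- function(geno) {
  stopifnot(is.matrix(geno))
  G <- geno * 1.0
  nas <- which(is.na(G), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    mu <- colMeans(G, na.rm = TRUE)
    G[nas] <- mu[nas[, 2]]
  }
  G
}

new_edm <- function(values, scale, ids) {
  structure(list(values = values, scale = scale, ids = ids),
            class = "mtsvr_edm")
}

#' Squared Euclidean distance matrix between marker vectors
#'
#' Computes the Hadamard-squared Euclidean distance matrix
#' \eqn{d_{ij} = \sum_l (m_{il} - m_{jl})^2} over all individuals, stored
#' together with its scale denominator (the number of markers `p`). The
#' squared distances are kept directly — the RBF kernel consumes them without
#' a square-root round trip.
#'
#' @param geno Complete genotype matrix (use [impute_genotypes()] first if
#'   there are missing calls). Raw 0/1/2 coding is fine: pairwise differences
#'   are invariant to column centering.
#' @return An `mtsvr_edm` object (`values`, `scale`, `ids`).
#' @export
sq_edm <- function(geno) {
  if (anyNA(geno))
    abort("`geno` has missing values; impute first (see `impute_genotypes()`)")
  X <- geno * 1.0
  sq <- rowSums(X^2)
  D <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
  D[D < 0] <- 0
  diag(D) <- 0
  D <- (D + t(D)) / 2
  new_edm(D, ncol(X), rownames(geno))
}

#' Weighted squared Euclidean distance matrix
#'
#' As [sq_edm()] but with per-locus weights:
#' \eqn{d_{ij} = \sum_l w_l (m_{il} - m_{jl})^2}, and scale denominator
#' \eqn{\sum_l w_l} replacing `p`. Used to emphasize loci with high
#' (co)variance contribution for a given trait pair.
#'
#' @param geno Complete genotype matrix.
#' @param w Length-`p` nonnegative weights in `[0, 1]`, not all zero.
#' @return An `mtsvr_edm` object.
#' @export
weighted_sq_edm <- function(geno, w) {
  if (anyNA(geno))
    abort("`geno` has missing values; impute first (see `impute_genotypes()`)")
  stopifnot(length(w) == ncol(geno), all(w >= 0))
  sw <- sum(w)
  if (sw <= 0) abort("all locus weights are zero; weighted distance undefined")
  X <- sweep(geno * 1.0, 2, sqrt(w), `*`)
  out <- sq_edm(X)
  out$scale <- sw
  out$ids <- rownames(geno)
  out
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' \eqn{G = Z Z' / (2 \sum_l q_l (1 - q_l))} with `Z` the genotype matrix
#' centered at twice the observed allele frequencies.
#'
#' @param geno Genotype matrix (0/1/2, `NA` mean-imputed internally).
#' @return A symmetric `N x N` matrix with the individuals' ids as dimnames.
#' @export
grm <- function(geno) {
  X <- impute_genotypes(geno)
  q <- colMeans(X) / 2
  denom <- 2 * sum(q * (1 - q))
  if (denom <= 0)
    abort("all SNPs are monomorphic; genomic relationship matrix undefined")
  Z <- sweep(X, 2, 2 * q, `-`)
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(geno), rownames(geno))
  G
}

#' Radial basis function kernel from a squared distance matrix
#'
#' \eqn{k_{ij} = \exp(-\theta \, d_{ij} / s)} where `d` holds squared
#' Euclidean distances and `s` is the stored scale denominator (`p`, or the
#' weight sum for weighted distances). Unit diagonal by construction.
#'
#' @param edm An `mtsvr_edm` from [sq_edm()] / [weighted_sq_edm()].
#' @param theta Bandwidth, `> 0`. Larger values decay similarity faster
#'   (more local kernels).
#' @return A symmetric kernel matrix with unit diagonal.
#' @export
rbf_kernel <- function(edm, theta) {
  stopifnot(inherits(edm, "mtsvr_edm"))
  if (theta <= 0) abort("`theta` must be > 0")
  K <- exp(-theta * edm$values / edm$scale)
  dimnames(K) <- list(edm$ids, edm$ids)
  K
}

pair_key <- function(k, kp) paste(min(k, kp), max(k, kp), sep = "_")

check_symmetric_hyper <- function(M, t, what, lo = -Inf, hi = Inf) {
  if (!is.matrix(M) || nrow(M) != t || ncol(M) != t)
    abort(sprintf("`%s` must be a %d x %d matrix", what, t, t))
  if (max(abs(M - t(M))) > 1e-12)
    abort(sprintf("`%s` must be symmetric (a valid kernel needs %s_kk' = %s_k'k)",
                  what, what, what))
  if (any(M < lo) || any(M > hi))
    abort(sprintf("`%s` entries must lie in [%s, %s]", what, lo, hi))
  invisible(M)
}

#' Multitask scaled RBF block kernel
#'
#' Assembles the `(N t) x (N t)` block kernel for `t` traits: diagonal blocks
#' `exp(-theta_kk D / s)`, off-diagonal blocks
#' `rho_kk' * exp(-theta_kk' D / s)`, laid out trait-major (all trait-1 rows,
#' then trait-2, ...). `theta` carries trait-specific (diagonal) and
#' trait-common (off-diagonal) bandwidths; `rho` shrinks the cross-trait
#' blocks by the assumed strength and direction of the association between
#' traits.
#'
#' @param dist A single `mtsvr_edm` used for every block, or a named list
#'   keyed `"k_k'"` (e.g. `"1_1"`, `"1_2"`, `"2_2"`) of per-pair distances
#'   (the weighted variant).
#' @param theta `t x t` symmetric matrix of positive bandwidths.
#' @param rho `t x t` symmetric matrix, unit diagonal, off-diagonals in
#'   `[-1, 1]`.
#' @return An `mtsvr_mt_kernel` object with elements `values`, `n`, `t`,
#'   `ids`, `theta`, `rho`, `jitter`.
#' @export
mt_kernel <- function(dist, theta, rho = NULL) {
  if (inherits(dist, "mtsvr_edm")) {
    t <- if (is.matrix(theta)) nrow(theta) else 1L
    keys <- outer(seq_len(t), seq_len(t), Vectorize(pair_key))
    dist_list <- setNames(rep(list(dist), length(unique(c(keys)))),
                          unique(c(keys)))
  } else {
    dist_list <- dist
    t <- if (is.matrix(theta)) nrow(theta) else 1L
  }
  if (!is.matrix(theta)) theta <- matrix(theta, 1, 1)
  if (is.null(rho)) rho <- diag(t)
  check_symmetric_hyper(theta, t, "theta", lo = 0)
  if (any(theta <= 0)) abort("`theta` entries must be > 0")
  check_symmetric_hyper(rho, t, "rho", lo = -1, hi = 1)
  if (max(abs(diag(rho) - 1)) > 1e-12) abort("`rho` must have unit diagonal")

  ref <- dist_list[[1]]
  n <- nrow(ref$values)
  ids <- ref$ids
  Q <- matrix(0, n * t, n * t)
  for (k in seq_len(t)) {
    for (kp in k:t) {
      dd <- dist_list[[pair_key(k, kp)]]
      if (is.null(dd)) abort(sprintf("no distance matrix for trait pair %d,%d", k, kp))
      blk <- rho[k, kp] * exp(-theta[k, kp] * dd$values / dd$scale)
      ri <- (k - 1L) * n + seq_len(n)
      ci <- (kp - 1L) * n + seq_len(n)
      Q[ri, ci] <- blk
      if (kp != k) Q[ci, ri] <- t(blk)
    }
  }
  structure(list(values = Q, n = n, t = t, ids = ids,
                 theta = theta, rho = rho, jitter = 0),
            class = "mtsvr_mt_kernel")
}

#' Stabilize a kernel to positive semidefiniteness by diagonal jitter
#'
#' The multitask block kernel with arbitrary bandwidths and cross-trait
#' scalings need not be positive semidefinite. If the smallest eigenvalue is
#' below `-min_eig_tol`, `|lambda_min| + 1e-8` is added to the diagonal (which
#' preserves all off-diagonal similarities) and the amount is recorded.
#'
#' @param K An `mtsvr_mt_kernel` or a plain symmetric matrix.
#' @param min_eig_tol Negative-eigenvalue tolerance below which repair kicks
#'   in.
#' @return Same type as the input; `mtsvr_mt_kernel` inputs carry the applied
#'   jitter in `$jitter`, matrices in `attr(, "jitter")`.
#' @export
stabilize_psd <- function(K, min_eig_tol = 1e-8) {
  M <- if (inherits(K, "mtsvr_mt_kernel")) K$values else K
  lambda_min <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  jit <- 0
  if (lambda_min < -min_eig_tol) {
    jit <- abs(lambda_min) + 1e-8
    M <- M + diag(jit, nrow(M))
  }
  if (inherits(K, "mtsvr_mt_kernel")) {
    K$values <- M
    K$jitter <- jit
    K
  } else {
    attr(M, "jitter") <- jit
    M
  }
}

#' @export
print.mtsvr_mt_kernel <- function(x, ...) {
  cat(sprintf("<mtsvr_mt_kernel> %d traits x %d individuals (%d x %d)\n",
              x$t, x$n, nrow(x$values), ncol(x$values)))
  cat("  theta:", paste(signif(x$theta[upper.tri(x$theta, diag = TRUE)], 3),
                        collapse = ", "), "\n")
  if (x$t > 1)
    cat("  rho:  ", paste(signif(x$rho[upper.tri(x$rho)], 3), collapse = ", "), "\n")
  if (x$jitter > 0) cat("  jitter applied:", signif(x$jitter, 3), "\n")
  invisible(x)
}

#' @export
print.mtsvr_edm <- function(x, ...) {
  cat(sprintf("<mtsvr_edm> %d x %d squared distances, scale denominator %.4g\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}
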