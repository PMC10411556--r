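#' Fit an epsilon-insensitive SVR on a precomputed kernel
#'
#' Solves the SVR dual on an arbitrary precomputed (single-trait or stacked
#' multitask) kernel by sequential minimal optimization: box constraints
#' `0 <= alpha_i, alpha*_i <= C` and the single equality constraint
#' `sum(alpha - alpha*) = 0` implied by one shared bias. The solution is kept
#' in the net-multiplier form `beta = alpha - alpha*` (complementarity makes
#' `alpha_i alpha*_i = 0` at the optimum). The bias is the average implied
#' bias over free support vectors (`0 < |beta| < C`), falling back to the
#' midpoint of the feasible bias interval when none are free. The solver is
#' deterministic: maximal-violating-pair selection with lowest-index
#' tie-breaks.
#'
#' @param K Symmetric PSD kernel over the training rows (apply
#'   [stabilize_psd()] first if in doubt), or an `mtsvr_mt_kernel`.
#' @param y Training responses (standardized scale for stacked problems).
#' @param cost Regularization constant `C > 0`.
#' @param epsilon Insensitivity half-width `>= 0` (residuals inside the tube
#'   are not penalized).
#' @param tol KKT violation tolerance for convergence.
#' @param max_iter Cap on pair updates; defaults to `1e4 * n` sweeps-worth.
#' @return An `mtsvr_svr` model: `beta` (net multipliers), `b0`, `sv` (support
#'   vector indices), `objective` (dual, maximization scale), `iterations`,
#'   `kkt_gap`, `fitted`, plus the training `y` and hyperparameters.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 20, 2)
#' K <- tcrossprod(X) / 2 + diag(20) # PSD toy kernel
#' y <- X[, 1] + rnorm(20, 0, 0.1)
#' m <- svr_fit(K, y, cost = 10, epsilon = 0.1)
#' glance(m)
svr_fit <- function(K, y, cost = 1, epsilon = 0.1, tol = 1e-3,
                    max_iter = NULL) {
  if (inherits(K, "mtsvr_mt_kernel")) K <- K$values
  n <- length(y)
  stopifnot(is.matrix(K), nrow(K) == n, ncol(K) == n,
            cost > 0, epsilon >= 0, tol > 0)
  if (anyNA(y)) abort("`y` has missing values")
  max_iter <- max_iter %||% (1e4 * n)
  fit <- .smo_fit(K, as.numeric(y), cost, epsilon, tol, max_iter)
  model <- structure(list(
    beta = as.numeric(fit$beta),
    b0 = fit$b0,
    sv = which(abs(as.numeric(fit$beta)) > 1e-12),
    objective = fit$objective,
    iterations = fit$iterations,
    converged = fit$converged,
    kkt_gap = fit$kkt_gap,
    fitted = as.numeric(fit$fitted_raw),
    y = as.numeric(y),
    ids = rownames(K),
    cost = cost, epsilon = epsilon, tol = tol
  ), class = "mtsvr_svr")
  if (!fit$converged)
    abort(sprintf("SMO did not converge in %g iterations (KKT gap %.3g)",
                  max_iter, fit$kkt_gap),
          class = "mtsvr_svr_nonconvergence", model = model)
  model
}

#' Predict from a fitted SVR via the dual representation
#'
#' `f(x) = K_cross %*% beta + b0`, on the training (standardized) scale: the
#' prediction depends only on kernel evaluations between test and training
#' rows and the dual solution.
#'
#' @param object An `mtsvr_svr` model.
#' @param K_cross Matrix of kernel evaluations, test rows by training
#'   columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mtsvr_svr <- function(object, K_cross, ...) {
  K_cross <- as.matrix(K_cross)
  if (ncol(K_cross) != length(object$beta))
    abort(sprintf("`K_cross` has %d columns but the model has %d training rows",
                  ncol(K_cross), length(object$beta)))
  as.numeric(K_cross %*% object$beta + object$b0)
}

#' KKT diagnostics for a fitted SVR
#'
#' Classifies every training row against the optimality conditions of the
#' epsilon-insensitive dual: rows with `beta = 0` must lie inside the tube
#' (residual at most `eps + tol` in absolute value), free rows
#' (`0 < |beta| < C`) must sit on the margin (residual equal to
#' `sign(beta) * eps`), and bound rows (`|beta| = C`) must lie on or outside
#' it.
#'
#' @param model An `mtsvr_svr` model.
#' @return A tibble with `row`, `beta`, `residual`, `status` (inside /
#'   margin / bound) and `violation`; the overall maximum violation is in
#'   `attr(, "max_violation")`.
#' @export
svr_kkt <- function(model) {
  stopifnot(inherits(model, "mtsvr_svr"))
  C <- model$cost; eps <- model$epsilon
  beta <- model$beta
  r <- model$y - model$fitted
  at_bound <- abs(abs(beta) - C) <= 1e-10
  is_zero <- abs(beta) <= 1e-12
  status <- dplyr::case_when(is_zero ~ "inside",
                             at_bound ~ "bound",
                             TRUE ~ "margin")
  violation <- numeric(length(beta))
  violation[is_zero] <- pmax(0, abs(r[is_zero]) - eps)
  free <- !is_zero & !at_bound
  violation[free] <- abs(r[free] - sign(beta[free]) * eps)
  up <- at_bound & beta > 0
  dn <- at_bound & beta < 0
  violation[up] <- pmax(0, eps - r[up])
  violation[dn] <- pmax(0, r[dn] + eps)
  out <- tibble(row = seq_along(beta), beta = beta, residual = r,
                status = status, violation = violation)
  attr(out, "max_violation") <- max(violation)
  out
}

#' @export
#' @method tidy mtsvr_svr
tidy.mtsvr_svr <- function(x, ...) {
  tibble(row = seq_along(x$beta),
         id = x$ids %||% as.character(seq_along(x$beta)),
         beta = x$beta,
         support = abs(x$beta) > 1e-12)
}

#' @export
#' @method glance mtsvr_svr
glance.mtsvr_svr <- function(x, ...) {
  tibble(n = length(x$beta), n_sv = length(x$sv), b0 = x$b0,
         objective = x$objective, iterations = x$iterations,
         kkt_gap = x$kkt_gap, converged = x$converged,
         cost = x$cost, epsilon = x$epsilon)
}

#' @export
print.mtsvr_svr <- function(x, ...) {
  cat(sprintf("<mtsvr_svr> n = %d, support vectors = %d, b0 = %.4g\n",
              length(x$beta), length(x$sv), x$b0))
  cat(sprintf("  C = %g, epsilon = %g, dual objective = %.6g (%g iterations)\n",
              x$cost, x$epsilon, x$objective, x$iterations))
  invisible(x)
}
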