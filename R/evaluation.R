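#' Corrected predictive accuracy
#'
#' Pearson correlation between observed and predicted values, divided by the
#' square root of the mean record reliability — the correction recovers
#' accuracy on the true-merit scale when the observed records are noisy
#' pseudo-phenotypes.
#'
#' @param y_obs,y_pred Numeric vectors (length >= 3, with variance).
#' @param mean_reliability Mean reliability of the observed records, in
#'   `(0, 1]`.
#' @return Scalar accuracy.
#' @export
acc <- function(y_obs, y_pred, mean_reliability = 1) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 3,
            mean_reliability > 0, mean_reliability <= 1)
  if (sd(y_obs) == 0 || sd(y_pred) == 0)
    abort("accuracy undefined: zero variance in observations or predictions")
  cor(y_obs, y_pred) / sqrt(mean_reliability)
}

#' Relative root-mean-square error
#'
#' RMSE of the predictions divided by the sample standard deviation of the
#' observations — dimensionless, 0 for perfect predictions and 1 for
#' predicting the observed mean (up to the sample/population SD factor).
#'
#' @param y_obs,y_pred Numeric vectors of equal length.
#' @return Scalar relative RMSE.
#' @export
rmse_star <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred))
  s <- sd(y_obs)
  if (!is.finite(s) || s == 0) abort("observations have zero variance")
  sqrt(mean((y_obs - y_pred)^2)) / s
}

#' Dispersion (inflation) coefficient
#'
#' Slope of the regression of realized observations on predictions,
#' `cov(y_obs, y_pred) / var(y_pred)`. Values above (below) 1 flag
#' upward- (downward-) biased prediction dispersion.
#'
#' @param y_obs,y_pred Numeric vectors of equal length.
#' @return Scalar slope.
#' @export
inflation_b <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred))
  v <- var(y_pred)
  if (!is.finite(v) || v == 0)
    abort("inflation undefined: predictions are constant")
  stats::cov(y_obs, y_pred) / v
}

#' Predictive-ability metrics for a prediction table
#'
#' Convenience wrapper computing [acc()], [rmse_star()] and [inflation_b()]
#' from a predictions tibble (as returned by [predict.mtsvr_qmtsvr()]),
#' optionally per generation for error-bar style breakdowns.
#'
#' @param predictions Tibble with `observed` and `.pred` columns (and
#'   `generation` when `by_generation = TRUE`).
#' @param mean_reliability Mean reliability of the observed records.
#' @param by_generation Also return one metric row per generation.
#' @param model Optional model label carried into the output.
#' @return A tibble of metrics.
#' @export
evaluate_predictions <- function(predictions, mean_reliability = 1,
                                 by_generation = FALSE, model = NULL) {
  one <- function(d, gen) {
    tibble(generation = gen,
           n = nrow(d),
           acc = acc(d$observed, d$.pred, mean_reliability),
           rmse_star = rmse_star(d$observed, d$.pred),
           b = inflation_b(d$observed, d$.pred))
  }
  out <- one(predictions, NA_integer_)
  if (by_generation) {
    per_gen <- predictions |>
      dplyr::group_by(.data$generation) |>
      dplyr::group_map(~ one(.x, .y$generation))
    out <- dplyr::bind_rows(out, per_gen)
  }
  if (!is.null(model)) out <- dplyr::mutate(out, model = model, .before = 1)
  out
}

#' Parametric accuracy from a bi-trait mixed model on the testing set
#'
#' Accuracy estimated free of environmental contamination: a bivariate
#' kernel mixed model is fitted to the testing set with the observed target
#' records as trait 1 and the model predictions as trait 2, and each
#' retained posterior draw yields `sqrt(h2 of the predictions) x genetic
#' correlation(observed, predicted)` — the selection-index estimate of
#' accuracy. Useful when CV2-style predictions may borrow environmental
#' signal from the indicator trait.
#'
#' @param y_obs,y_pred Observed and predicted target records of the test
#'   individuals (same order as `kernel_test` rows).
#' @param kernel_test Relationship kernel restricted to the test individuals
#'   (G by default choice; any PSD kernel works).
#' @param n_iter,burn_in,thin,seed Chain controls (see [mt_gblup()]).
#' @return An `mtsvr_acc_par` object holding the posterior draws.
#' @export
acc_par <- function(y_obs, y_pred, kernel_test,
                    n_iter = 20000, burn_in = 5000, thin = 5, seed = NULL) {
  stopifnot(length(y_obs) == length(y_pred),
            length(y_obs) == nrow(kernel_test))
  ids <- rownames(kernel_test) %||% sprintf("tst_%05d", seq_along(y_obs))
  rownames(kernel_test) <- colnames(kernel_test) <- ids
  phen <- tibble(id = ids, generation = 0L,
                 trait_1 = y_obs, trait_2 = y_pred)
  fit <- mt_gblup(phen, kernel_test, traits = c(1, 2),
                  n_iter = n_iter, burn_in = burn_in, thin = thin,
                  seed = seed)
  draws <- sqrt(fit$draws$h2_2) * fit$draws$r_g_12
  structure(list(draws = draws, model = fit), class = "mtsvr_acc_par")
}

#' Posterior contrast between two parametric accuracies
#'
#' Pairs the retained draws of two independently fitted [acc_par()] chains by
#' draw index (truncating to the shorter chain), returns the difference
#' draws and the posterior probability that the difference is negative —
#' small values favour model A.
#'
#' @param a,b `mtsvr_acc_par` objects (or bare draw vectors).
#' @return List with `draws` (lambda = A - B) and `p_negative`.
#' @export
acc_par_contrast <- function(a, b) {
  da <- if (inherits(a, "mtsvr_acc_par")) a$draws else as.numeric(a)
  db <- if (inherits(b, "mtsvr_acc_par")) b$draws else as.numeric(b)
  n <- min(length(da), length(db))
  lambda <- da[seq_len(n)] - db[seq_len(n)]
  list(draws = lambda, p_negative = mean(lambda < 0))
}

#' @export
#' @method tidy mtsvr_acc_par
tidy.mtsvr_acc_par <- function(x, ...) {
  tibble(draw = seq_along(x$draws), acc_par = x$draws)
}

#' @export
#' @method glance mtsvr_acc_par
glance.mtsvr_acc_par <- function(x, ...) {
  q <- stats::quantile(x$draws, c(0.025, 0.975))
  tibble(mean = mean(x$draws), sd = sd(x$draws),
         ci_low = q[[1]], ci_high = q[[2]], n_draws = length(x$draws))
}

#' @export
print.mtsvr_acc_par <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<mtsvr_acc_par> posterior mean %.3f (sd %.3f, 95%% CI [%.3f, %.3f])\n",
              g$mean, g$sd, g$ci_low, g$ci_high))
  invisible(x)
}
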