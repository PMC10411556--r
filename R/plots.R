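#' Plot the fitness trajectory of a GA tuning run
#'
#' Best-so-far and population-mean fitness (inner-validation correlation)
#' across GA generations; downward wobbles of the mean reflect exploratory
#' crossover/mutation, while the best line is non-decreasing under elitism.
#'
#' @param object An `mtsvr_ga` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mtsvr_ga <- function(object, ...) {
  d <- object$history |>
    tidyr::pivot_longer(c("best_fs", "mean_fs"),
                        names_to = "series", values_to = "fitness") |>
    dplyr::mutate(series = dplyr::recode(.data$series,
                                         best_fs = "best so far",
                                         mean_fs = "population mean"))
  ggplot2::ggplot(d, ggplot2::aes(.data$generation, .data$fitness,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "GA generation", y = "fitness (validation r)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot observed versus predicted values for a fitted QMTSVR
#'
#' @param object An `mtsvr_qmtsvr` model.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mtsvr_qmtsvr <- function(object, ...) {
  d <- predict(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$.pred, .data$observed)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "predicted", y = "observed") +
    ggplot2::theme_minimal()
}

#' Histogram of off-diagonal kernel block entries
#'
#' Shows how the bandwidths and cross-trait scalings shape the similarity
#' distribution in each block of the multitask kernel (diagonal entries are
#' omitted).
#'
#' @param object An `mtsvr_mt_kernel`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mtsvr_mt_kernel <- function(object, bins = 50, ...) {
  n <- object$n
  t <- object$t
  pieces <- list()
  for (k in seq_len(t)) for (kp in k:t) {
    blk <- object$values[(k - 1) * n + seq_len(n), (kp - 1) * n + seq_len(n)]
    v <- if (k == kp) blk[upper.tri(blk)] else as.numeric(blk)
    pieces[[length(pieces) + 1]] <- tibble(
      block = sprintf("block (%d,%d)", k, kp), value = v)
  }
  ggplot2::ggplot(dplyr::bind_rows(pieces), ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(~block, scales = "free_y") +
    ggplot2::labs(x = "kernel entry", y = "count") +
    ggplot2::theme_minimal()
}

#' Manhattan-style track of locus weights
#'
#' @param object A [locus_weights()] vector.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_locus_weights <- function(object, ...) {
  pair <- attr(object, "pair")
  d <- tibble(locus = seq_along(object), weight = as.numeric(object))
  ggplot2::ggplot(d, ggplot2::aes(.data$locus, .data$weight)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(title = if (!is.null(pair))
      sprintf("locus weights, trait pair (%d, %d)", pair[1], pair[2]) else NULL,
      x = "locus index", y = "normalized (co)variance weight") +
    ggplot2::theme_minimal()
}

#' Posterior density of parametric accuracy draws
#'
#' @param object An `mtsvr_acc_par`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mtsvr_acc_par <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$acc_par)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(xintercept = mean(object$draws), linetype = 2) +
    ggplot2::labs(x = "parametric accuracy", y = "posterior density") +
    ggplot2::theme_minimal()
}
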