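#' Stack multi-trait records into a single-response training set
#'
#' Implements the data-expansion scheme behind (quasi) multitask SVR: the
#' records of `t` traits are stacked into one response vector (trait-major
#' order), standardized per trait by z-score using training-row statistics
#' only, and tagged with their role under the chosen validation design:
#'
#' * `ST` — train rows are the target-trait records of training individuals
#'   only;
#' * `CV1` — train rows are all traits' records of training individuals
#'   (test individuals contribute no records);
#' * `CV2` — the CV1 rows plus the secondary-trait records of test
#'   individuals (the indicator traits are measured on everyone).
#'
#' Predict rows are the target-trait records of test individuals in every
#' design. Individuals missing a secondary-trait record are omitted from
#' that trait's block; a missing target record among training individuals is
#' an error.
#'
#' @param phenotypes Phenotype tibble (`id`, `generation`, `trait_*`).
#' @param split An [forward_split()] object (or any list with `train_ids` /
#'   `test_ids`).
#' @param target_trait Trait number of the prediction target (column
#'   `trait_<k>`).
#' @param design One of `"ST"`, `"CV1"`, `"CV2"`.
#' @param traits Trait numbers included in the stack (defaults to all
#'   `trait_*` columns for CV1/CV2, the target alone for ST). The block order
#'   of the multitask kernel follows this vector.
#' @return An `mtsvr_stack`: `rows` tibble (`id`, `generation`, `trait`,
#'   `trait_pos`, `role`, `y`, `y_star`), `standardizers` tibble, plus design
#'   metadata.
#' @export
stack_traits <- function(phenotypes, split, target_trait = 1,
                         design = c("CV1", "CV2", "ST"), traits = NULL) {
  design <- match.arg(design)
  trait_cols <- grep("^trait_", names(phenotypes), value = TRUE)
  all_traits <- as.integer(sub("^trait_", "", trait_cols))
  if (is.null(traits))
    traits <- if (design == "ST") target_trait else all_traits
  if (design == "ST") traits <- target_trait
  if (!target_trait %in% traits)
    abort("`target_trait` must be among `traits`")
  if (!all(traits %in% all_traits))
    abort("some `traits` have no matching `trait_*` column")

  grab <- function(ids, k, role) {
    d <- phenotypes[match(ids, phenotypes$id), ]
    tibble(id = d$id,
           generation = d$generation,
           trait = k,
           trait_pos = match(k, traits),
           role = role,
           y = d[[paste0("trait_", k)]])
  }

  rows <- list()
  for (k in traits) {
    tr <- grab(split$train_ids, k, "train")
    if (k == target_trait) {
      if (anyNA(tr$y))
        abort(sprintf("design %s requires the target trait observed for all training individuals",
                      design))
    } else {
      tr <- tr[!is.na(tr$y), ]
    }
    rows[[length(rows) + 1]] <- tr
    if (design == "CV2" && k != target_trait && length(split$test_ids) > 0) {
      te <- grab(split$test_ids, k, "train")
      if (anyNA(te$y))
        abort("CV2 requires the secondary trait observed for test individuals")
      rows[[length(rows) + 1]] <- te
    }
  }
  train_rows <- dplyr::bind_rows(rows)
  pred_rows <- grab(split$test_ids, target_trait, "predict")

  std <- train_rows |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(mean = mean(.data$y), sd = sd(.data$y), .groups = "drop")
  if (any(!is.finite(std$sd)) || any(std$sd <= 0))
    abort("zero or undefined standard deviation among training rows")

  train_rows <- train_rows |>
    dplyr::left_join(std, by = "trait") |>
    dplyr::mutate(y_star = (.data$y - .data$mean) / .data$sd) |>
    dplyr::select(-"mean", -"sd")
  pred_rows$y_star <- NA_real_

  structure(list(rows = dplyr::bind_rows(train_rows, pred_rows),
                 standardizers = std,
                 target_trait = target_trait,
                 traits = traits, design = design),
            class = "mtsvr_stack")
}

#' Extract training and cross kernels for a stacked dataset
#'
#' Picks, from the full multitask block kernel, the entries matching each
#' stacked row's (individual, trait) pair: `K_train` follows the train-row
#' order, `K_cross` has predict rows against train columns.
#'
#' @param kernel An `mtsvr_mt_kernel` built over (at least) all stacked
#'   individuals, with blocks ordered like the stack's `traits`.
#' @param stack An [stack_traits()] object.
#' @return List with `K_train` and `K_cross`.
#' @export
assemble_q <- function(kernel, stack) {
  stopifnot(inherits(kernel, "mtsvr_mt_kernel"), inherits(stack, "mtsvr_stack"))
  if (length(stack$traits) != kernel$t)
    abort("kernel block count does not match the number of stacked traits")
  pos <- match(stack$rows$id, kernel$ids)
  if (anyNA(pos))
    abort("some stacked individuals are absent from the kernel's id set")
  idx <- (stack$rows$trait_pos - 1L) * kernel$n + pos
  is_train <- stack$rows$role == "train"
  list(K_train = kernel$values[idx[is_train], idx[is_train], drop = FALSE],
       K_cross = kernel$values[idx[!is_train], idx[is_train], drop = FALSE])
}

build_pair_distances <- function(genotypes, traits, weights = NULL) {
  X <- impute_genotypes(genotypes)
  t <- length(traits)
  if (is.null(weights)) {
    d <- sq_edm(X)
    d$ids <- rownames(genotypes)
    keys <- unique(c(outer(seq_len(t), seq_len(t), Vectorize(pair_key))))
    return(setNames(rep(list(d), length(keys)), keys))
  }
  out <- list()
  for (k in seq_len(t)) for (kp in k:t) {
    key <- pair_key(k, kp)
    w <- weights[[pair_key(traits[k], traits[kp])]]
    if (is.null(w))
      abort(sprintf("no locus weights supplied for trait pair (%d,%d)",
                    traits[k], traits[kp]))
    d <- weighted_sq_edm(X, as.numeric(w))
    d$ids <- rownames(genotypes)
    out[[key]] <- d
  }
  out
}

#' Fit a (quasi) multitask SVR for genomic prediction
#'
#' End-to-end fit: builds (plain or SNP-weighted) squared-distance matrices
#' over all genotyped individuals, assembles the multitask scaled RBF block
#' kernel, repairs positive semidefiniteness by diagonal jitter if needed,
#' stacks the standardized responses per the validation design and solves the
#' epsilon-SVR dual by SMO. With one trait this reduces exactly to a
#' single-trait SVR on the RBF kernel (or on a supplied precomputed kernel,
#' e.g. the genomic relationship matrix for a linear SVR).
#'
#' @param genotypes Genotype matrix covering all training and test
#'   individuals (ignored when `dist` or `kernel` is supplied).
#' @param phenotypes Phenotype tibble.
#' @param split [forward_split()] result.
#' @param target_trait Trait number to predict.
#' @param design `"ST"`, `"CV1"` or `"CV2"`.
#' @param theta Bandwidths: scalar for one trait, `t x t` symmetric matrix
#'   otherwise.
#' @param rho Cross-trait association constants (`t x t`, unit diagonal);
#'   identity if omitted.
#' @param cost,epsilon SVR regularization and tube half-width.
#' @param traits Trait numbers stacked (see [stack_traits()]).
#' @param weights Optional named list of per-pair locus weights (from
#'   [pair_weights()], estimated on training data) for the weighted variant.
#' @param dist Optional precomputed distances: an `mtsvr_edm` or per-pair
#'   list, to avoid recomputation across fits (as in tuning loops).
#' @param kernel Optional precomputed `N x N` kernel matrix over individuals
#'   (single-trait designs only), e.g. [grm()] output for a linear SVR.
#' @param tol,max_iter Solver controls; `psd_tol` the PSD repair tolerance.
#' @param psd_tol Negative-eigenvalue tolerance before jitter repair.
#' @return An `mtsvr_qmtsvr` model.
#' @export
qmtsvr_fit <- function(genotypes = NULL, phenotypes, split,
                       target_trait = 1, design = c("CV1", "CV2", "ST"),
                       theta = NULL, rho = NULL, cost = 1, epsilon = 0.01,
                       traits = NULL, weights = NULL, dist = NULL,
                       kernel = NULL, tol = 1e-3, max_iter = NULL,
                       psd_tol = 1e-8) {
  design <- match.arg(design)
  stack <- stack_traits(phenotypes, split, target_trait, design, traits)
  t <- length(stack$traits)

  if (!is.null(kernel)) {
    if (t != 1)
      abort("a precomputed `kernel` matrix is supported for single-trait designs only")
    ids <- rownames(kernel)
    Q <- structure(list(values = kernel, n = nrow(kernel), t = 1L,
                        ids = ids, theta = matrix(NA_real_, 1, 1),
                        rho = matrix(1, 1, 1), jitter = 0),
                   class = "mtsvr_mt_kernel")
  } else {
    if (is.null(theta)) abort("`theta` is required unless `kernel` is given")
    if (!is.matrix(theta)) theta <- matrix(theta, t, t)
    if (is.null(dist)) {
      if (is.null(genotypes)) abort("supply `genotypes` or precomputed `dist`")
      dist <- build_pair_distances(genotypes, stack$traits, weights)
    } else if (inherits(dist, "mtsvr_edm")) {
      keys <- unique(c(outer(seq_len(t), seq_len(t), Vectorize(pair_key))))
      dist <- setNames(rep(list(dist), length(keys)), keys)
    }
    Q <- mt_kernel(dist, theta, rho)
  }
  Q <- stabilize_psd(Q, psd_tol)

  mats <- assemble_q(Q, stack)
  is_train <- stack$rows$role == "train"
  svr <- svr_fit(mats$K_train, stack$rows$y_star[is_train],
                 cost = cost, epsilon = epsilon, tol = tol,
                 max_iter = max_iter)
  structure(list(svr = svr, stack = stack, K_cross = mats$K_cross,
                 theta = Q$theta, rho = Q$rho, jitter = Q$jitter,
                 design = design, target_trait = target_trait,
                 weighted = !is.null(weights)),
            class = "mtsvr_qmtsvr")
}

#' Predict the target trait for the test individuals
#'
#' Applies the dual predictor to the stored test-by-train kernel rows and
#' returns predictions de-standardized with the target trait's training
#' mean and standard deviation.
#'
#' @param object An `mtsvr_qmtsvr` model.
#' @param ... Unused.
#' @return Tibble `id`, `generation`, `observed`, `.pred` (original scale).
#' @export
predict.mtsvr_qmtsvr <- function(object, ...) {
  stack <- object$stack
  pred_rows <- stack$rows[stack$rows$role == "predict", ]
  raw <- predict(object$svr, object$K_cross)
  std <- stack$standardizers[stack$standardizers$trait == stack$target_trait, ]
  tibble(id = pred_rows$id,
         generation = pred_rows$generation,
         observed = pred_rows$y,
         .pred = std$mean + std$sd * raw)
}

#' @export
#' @method glance mtsvr_qmtsvr
glance.mtsvr_qmtsvr <- function(x, ...) {
  dplyr::bind_cols(
    tibble(design = x$design, target_trait = x$target_trait,
           weighted = x$weighted, jitter = x$jitter),
    glance(x$svr))
}

#' @export
#' @method tidy mtsvr_qmtsvr
tidy.mtsvr_qmtsvr <- function(x, ...) {
  rows <- x$stack$rows[x$stack$rows$role == "train", ]
  dplyr::bind_cols(rows[, c("id", "generation", "trait")],
                   tidy(x$svr)[, c("beta", "support")])
}

#' @export
print.mtsvr_qmtsvr <- function(x, ...) {
  cat(sprintf("<mtsvr_qmtsvr> design %s, target trait %d, %d stacked traits%s\n",
              x$design, x$target_trait, length(x$stack$traits),
              if (x$weighted) " (weighted kernel)" else ""))
  print(x$svr)
  invisible(x)
}
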