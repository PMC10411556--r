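#' Hyperparameter search space for QMTSVR tuning
#'
#' Defines per-parameter bounds and binary-encoding resolution for the
#' genetic-algorithm search. For `t` traits the tunable set is the global
#' `C` and `epsilon`, one bandwidth per unordered trait pair (`t(t+1)/2`
#' values) and one association constant `rho` per distinct pair — `2 + t^2`
#' parameters in total. Fixing `rho` a priori (e.g. at the known genetic
#' correlation) removes those dimensions, leaving `2 + t(t+1)/2`.
#'
#' Default bounds: `C` in `[0.1, 4]`, `epsilon` in `[1e-4, 0.1]`, bandwidths
#' in `[0.2, 7]`, `rho` in `[0.1, 0.3]`.
#'
#' @param n_traits Number of stacked traits.
#' @param rho_fixed Optional `t x t` matrix (or scalar for `t = 2`) of fixed
#'   association constants; removes `rho` from the search.
#' @param cost_bounds,epsilon_bounds,theta_bounds,rho_bounds Length-2 bounds.
#' @param n_bits Bits per parameter (encoding resolution).
#' @return An `mtsvr_space` tibble (`name`, `lower`, `upper`, `n_bits`) with
#'   attributes `n_traits` and `rho_fixed`.
#' @export
qmtsvr_space <- function(n_traits = 2, rho_fixed = NULL,
                         cost_bounds = c(0.1, 4),
                         epsilon_bounds = c(1e-4, 0.1),
                         theta_bounds = c(0.2, 7),
                         rho_bounds = c(0.1, 0.3),
                         n_bits = 8L) {
  t <- n_traits
  rows <- list(tibble(name = "cost", lower = cost_bounds[1], upper = cost_bounds[2]),
               tibble(name = "epsilon", lower = epsilon_bounds[1], upper = epsilon_bounds[2]))
  for (k in seq_len(t)) for (kp in k:t)
    rows[[length(rows) + 1]] <- tibble(name = sprintf("theta_%d_%d", k, kp),
                                       lower = theta_bounds[1], upper = theta_bounds[2])
  if (is.null(rho_fixed) && t > 1) {
    for (k in seq_len(t - 1)) for (kp in (k + 1):t)
      rows[[length(rows) + 1]] <- tibble(name = sprintf("rho_%d_%d", k, kp),
                                         lower = rho_bounds[1], upper = rho_bounds[2])
  }
  space <- dplyr::bind_rows(rows)
  space$n_bits <- as.integer(n_bits)
  stopifnot(all(space$lower < space$upper), all(space$n_bits >= 1))
  if (!is.null(rho_fixed))
    rho_fixed <- as_corr_spec(rho_fixed, t)
  structure(space, class = c("mtsvr_space", class(space)),
            n_traits = t, rho_fixed = rho_fixed)
}

# rho matrices here need symmetry and unit diagonal but not positive
# definiteness (the kernel is PSD-repaired downstream)
as_corr_spec <- function(x, t) {
  if (is.matrix(x)) R <- x
  else if (length(x) == 1 && t == 2) R <- matrix(c(1, x, x, 1), 2, 2)
  else abort("`rho_fixed` must be a scalar (t = 2) or a t x t matrix")
  check_symmetric_hyper(R, t, "rho", lo = -1, hi = 1)
  R
}

#' Decode a binary chromosome into hyperparameter values
#'
#' Each parameter occupies `n_bits` positions (most significant first); the
#' integer value maps linearly onto `[lower, upper]`:
#' `lower + int / (2^n_bits - 1) * (upper - lower)`. All-zero bits hit the
#' lower bounds exactly, all-one bits the upper bounds.
#'
#' @param bits 0/1 vector of length `sum(space$n_bits)`.
#' @param space An [qmtsvr_space()] object.
#' @return Named list of parameter values plus `theta` / `rho` matrices
#'   assembled for [qmtsvr_fit()].
#' @export
decode_chromosome <- function(bits, space) {
  if (length(bits) != sum(space$n_bits))
    abort(sprintf("chromosome has %d bits; the space needs %d",
                  length(bits), sum(space$n_bits)))
  t <- attr(space, "n_traits")
  vals <- numeric(nrow(space))
  pos <- 0L
  for (i in seq_len(nrow(space))) {
    b <- space$n_bits[i]
    seg <- bits[pos + seq_len(b)]
    int <- sum(seg * 2^((b - 1):0))
    vals[i] <- space$lower[i] + int / (2^b - 1) * (space$upper[i] - space$lower[i])
    pos <- pos + b
  }
  names(vals) <- space$name
  out <- as.list(vals)
  if (!is.null(t) && all(sprintf("theta_%d_%d", seq_len(t), seq_len(t)) %in%
                         space$name)) {
    theta <- matrix(0, t, t)
    for (k in seq_len(t)) for (kp in k:t)
      theta[k, kp] <- theta[kp, k] <- vals[[sprintf("theta_%d_%d", k, kp)]]
    rho <- attr(space, "rho_fixed")
    if (is.null(rho)) {
      rho <- diag(t)
      if (t > 1) for (k in seq_len(t - 1)) for (kp in (k + 1):t) {
        nm <- sprintf("rho_%d_%d", k, kp)
        if (nm %in% names(vals)) rho[k, kp] <- rho[kp, k] <- vals[[nm]]
      }
    }
    out <- c(out, list(theta = theta, rho = rho))
  }
  out
}

#' Tournament selection
#'
#' Draws `tsize` population indices uniformly with replacement and returns
#' the index of the highest-fitness draw; ties break to the lowest population
#' index.
#'
#' @param fitness Numeric fitness vector of the current population.
#' @param tsize Tournament size.
#' @return The selected index.
#' @export
ga_tournament <- function(fitness, tsize) {
  cand <- sort(sample.int(length(fitness), tsize, replace = TRUE))
  cand[which.max(fitness[cand])]
}

#' Two-point crossover and bitwise mutation
#'
#' With probability `cr`, two cut points are chosen uniformly and the middle
#' segment of parent 1 is replaced by parent 2's (2-point crossover);
#' otherwise the child is a copy of one parent chosen uniformly. Each bit of
#' the result then flips independently with probability `mr`.
#'
#' @param p1,p2 Equal-length 0/1 parent chromosomes.
#' @param cr Crossover rate.
#' @param mr Per-bit mutation rate.
#' @return The child chromosome.
#' @export
ga_crossover <- function(p1, p2, cr, mr) {
  stopifnot(length(p1) == length(p2))
  L <- length(p1)
  child <- if (runif(1) < cr && L >= 2) {
    cuts <- sort(sample.int(L - 1, 2))
    mid <- (cuts[1] + 1):cuts[2]
    out <- p1
    out[mid] <- p2[mid]
    out
  } else if (runif(1) < 0.5) p1 else p2
  flip <- runif(L) < mr
  child[flip] <- 1L - child[flip]
  child
}

# fitness ties break toward smaller C, then the smaller chromosome integer
ga_better <- function(fs_a, bits_a, fs_b, bits_b, space) {
  if (fs_a != fs_b) return(fs_a > fs_b)
  ca <- decode_chromosome(bits_a, space)$cost
  cb <- decode_chromosome(bits_b, space)$cost
  if (!is.null(ca) && !is.null(cb) && ca != cb) return(ca < cb)
  paste(bits_a, collapse = "") < paste(bits_b, collapse = "")
}

#' Genetic-algorithm maximization over a binary-encoded parameter space
#'
#' Generic GA engine: a population of binary chromosomes is evaluated,
#' parents are chosen by tournament selection, children are produced by
#' two-point crossover and bitwise mutation, and the `elitism` best
#' chromosomes of each generation replace the worst children of the next —
#' so best-so-far fitness is non-decreasing. Identical seeds replay
#' identically. Duplicated chromosomes are looked up in a fitness cache
#' rather than re-evaluated, without changing the
#' `pop_size x n_generations` candidate accounting. Fitness ties break
#' toward smaller `cost` (when the space has one), then the smaller
#' chromosome integer — a deterministic preference for simpler models.
#'
#' @param fitness Function taking the decoded parameter list (see
#'   [decode_chromosome()]) and returning a scalar fitness to maximize;
#'   non-finite values are mapped to −1.
#' @param space An [qmtsvr_space()] (or any tibble with `name`, `lower`,
#'   `upper`, `n_bits` and an `n_traits` attribute).
#' @param n_generations,pop_size,crossover_rate,mutation_rate,tournament_size
#'   GA controls (defaults 30, 25, 0.9, 0.05, 4).
#' @param elitism Number of elite chromosomes carried over (default 1).
#' @param seed Integer seed governing the whole run.
#' @return An `mtsvr_ga` object: `best` (decoded parameters),
#'   `best_fitness`, `best_bits`, `history` tibble (`generation`, `best_fs`,
#'   `mean_fs`), `n_models_evaluated`, `space`.
#' @export
ga_optimize <- function(fitness, space,
                        n_generations = 30, pop_size = 25,
                        crossover_rate = 0.9, mutation_rate = 0.05,
                        tournament_size = 4, elitism = 1, seed = NULL) {
  stopifnot(pop_size >= tournament_size, tournament_size >= 2,
            elitism >= 0, elitism < pop_size)
  if (!is.null(seed)) set.seed(seed)

  fitness_of <- function(bits) {
    fs <- tryCatch(fitness(decode_chromosome(bits, space)),
                   error = function(e) NA_real_)
    if (!is.finite(fs)) -1 else fs
  }
  cache <- new.env(parent = emptyenv())
  eval_cached <- function(bits) {
    key <- paste(bits, collapse = "")
    if (is.null(cache[[key]])) cache[[key]] <- fitness_of(bits)
    cache[[key]]
  }

  L <- sum(space$n_bits)
  pop <- lapply(seq_len(pop_size), function(i) as.integer(runif(L) < 0.5))
  history <- vector("list", n_generations)
  best_bits <- NULL
  best_fs <- -Inf
  n_eval <- 0L

  for (g in seq_len(n_generations)) {
    fs <- vapply(pop, eval_cached, numeric(1))
    n_eval <- n_eval + pop_size

    for (i in seq_len(pop_size)) {
      if (is.null(best_bits) ||
          ga_better(fs[i], pop[[i]], best_fs, best_bits, space)) {
        best_fs <- fs[i]
        best_bits <- pop[[i]]
      }
    }
    hp_best <- decode_chromosome(best_bits, space)
    history[[g]] <- tibble(generation = g, best_fs = best_fs,
                           mean_fs = mean(fs),
                           cost = hp_best$cost %||% NA_real_,
                           epsilon = hp_best$epsilon %||% NA_real_)

    if (g == n_generations) break

    children <- lapply(seq_len(pop_size), function(i) {
      p1 <- pop[[ga_tournament(fs, tournament_size)]]
      p2 <- pop[[ga_tournament(fs, tournament_size)]]
      ga_crossover(p1, p2, crossover_rate, mutation_rate)
    })
    if (elitism > 0) {
      child_fs <- vapply(children, eval_cached, numeric(1))
      worst <- order(child_fs)[seq_len(elitism)]
      elite <- order(fs, decreasing = TRUE)[seq_len(elitism)]
      for (j in seq_len(elitism)) children[[worst[j]]] <- pop[[elite[j]]]
    }
    pop <- children
  }

  structure(list(best = decode_chromosome(best_bits, space),
                 best_fitness = best_fs,
                 best_bits = best_bits,
                 history = dplyr::bind_rows(history),
                 n_models_evaluated = n_eval,
                 space = space,
                 config = list(n_generations = n_generations,
                               pop_size = pop_size,
                               crossover_rate = crossover_rate,
                               mutation_rate = mutation_rate,
                               tournament_size = tournament_size,
                               elitism = elitism, seed = seed)),
            class = "mtsvr_ga")
}

#' Genetic-algorithm hyperparameter tuning for QMTSVR
#'
#' Maximizes the Pearson correlation between observed and predicted
#' target-trait records on an inner forward-validation window held out
#' within the training generations: each candidate hyperparameter set is
#' decoded, the model is fitted on the inner-training rows and scored on the
#' inner-validation rows (solver failures or degenerate predictions map to
#' fitness −1). Distances are computed once and shared across all candidate
#' fits. See [ga_optimize()] for the engine.
#'
#' @param genotypes,phenotypes,target_trait,design,traits,weights As in
#'   [qmtsvr_fit()].
#' @param split A [forward_split()] with `inner_train_ids` / `inner_val_ids`
#'   (pass `inner_validation =` when splitting).
#' @param space An [qmtsvr_space()].
#' @param n_generations,pop_size,crossover_rate,mutation_rate,tournament_size,elitism,seed
#'   Passed to [ga_optimize()].
#' @param dist Optional precomputed distances (else computed once here).
#' @return An `mtsvr_ga` object (see [ga_optimize()]); `best$theta` /
#'   `best$rho` feed straight into [qmtsvr_fit()] for retraining on the full
#'   training window.
#' @export
qmtsvr_tune <- function(genotypes = NULL, phenotypes, split,
                        target_trait = 1, design = c("CV1", "CV2", "ST"),
                        space = qmtsvr_space(), traits = NULL, weights = NULL,
                        n_generations = 30, pop_size = 25,
                        crossover_rate = 0.9, mutation_rate = 0.05,
                        tournament_size = 4, elitism = 1,
                        seed = NULL, dist = NULL) {
  design <- match.arg(design)
  if (is.null(split$inner_train_ids) || is.null(split$inner_val_ids))
    abort("`split` needs an inner validation window (see `forward_split(inner_validation=)`)")

  t <- attr(space, "n_traits")
  inner_split <- list(train_ids = split$inner_train_ids,
                      test_ids = split$inner_val_ids)
  stack_probe <- stack_traits(phenotypes, inner_split, target_trait, design,
                              traits)
  if (length(stack_probe$traits) != t)
    abort(sprintf("search space is for %d traits but the stack has %d",
                  t, length(stack_probe$traits)))
  if (is.null(dist)) {
    ids_needed <- unique(c(split$inner_train_ids, split$inner_val_ids))
    dist <- build_pair_distances(genotypes[ids_needed, , drop = FALSE],
                                 stack_probe$traits, weights)
  }

  fitness <- function(hp) {
    fit <- qmtsvr_fit(phenotypes = phenotypes, split = inner_split,
                      target_trait = target_trait, design = design,
                      theta = hp$theta, rho = hp$rho,
                      cost = hp$cost, epsilon = hp$epsilon,
                      traits = traits, dist = dist)
    pr <- predict(fit)
    suppressWarnings(cor(pr$observed, pr$.pred))
  }

  ga_optimize(fitness, space,
              n_generations = n_generations, pop_size = pop_size,
              crossover_rate = crossover_rate, mutation_rate = mutation_rate,
              tournament_size = tournament_size, elitism = elitism,
              seed = seed)
}

#' @export
#' @method tidy mtsvr_ga
tidy.mtsvr_ga <- function(x, ...) x$history

#' @export
#' @method glance mtsvr_ga
glance.mtsvr_ga <- function(x, ...) {
  hp <- x$best
  tibble(best_fitness = x$best_fitness,
         cost = hp$cost, epsilon = hp$epsilon,
         n_models_evaluated = x$n_models_evaluated,
         n_generations = x$config$n_generations,
         pop_size = x$config$pop_size)
}

#' @export
print.mtsvr_ga <- function(x, ...) {
  cat(sprintf("<mtsvr_ga> %d generations x %d chromosomes (%d candidate models)\n",
              x$config$n_generations, x$config$pop_size, x$n_models_evaluated))
  cat(sprintf("  best fitness (inner-validation r): %.4f\n", x$best_fitness))
  cat(sprintf("  C = %.3f, epsilon = %.4f\n", x$best$cost, x$best$epsilon))
  cat("  theta:", paste(signif(x$best$theta[upper.tri(x$best$theta, diag = TRUE)], 3),
                        collapse = ", "), "\n")
  if (nrow(x$best$rho) > 1)
    cat("  rho:  ", paste(signif(x$best$rho[upper.tri(x$best$rho)], 3),
                          collapse = ", "), "\n")
  invisible(x)
}
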