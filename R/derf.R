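# Hybrid differential-evolution / random-forest parameter estimation.
#
# Individuals are multiplicative fold-change vectors over the unknown
# parameters, each coordinate bounded to [0.066, 1.906]. The DE mutation rule
# is x_new = x_p + F (x_q - x_r) with e(x_q) < e(x_r), F uniform on [0.2, 1],
# no crossover; a candidate joins the population only if its prediction error
# is strictly below the current population median. Periodically, random
# forests trained on a principal-component reduction of the evaluated
# phenotypes propose inverse estimates that are injected through the same
# acceptance rule.

#' Configuration for the DE-RF estimator
#'
#' @param pop_size initial population size (default 200).
#' @param f_range range of the DE scale factor F (default `c(0.2, 1)`).
#' @param bounds per-coordinate fold-change bounds (default
#'   `c(0.066, 1.906)`).
#' @param budget total number of candidate evaluations.
#' @param pop_cap population cap; the worst member is evicted beyond it.
#' @param rf_period evaluations between random-forest injection epochs.
#' @param rf_count proposals injected per epoch.
#' @param pca_target cumulative explained-variance target (default 0.40).
#' @param pca_min minimum retained components (the reduction is meant to keep
#'   several dozen axes; with few measurements the variance target alone can
#'   collapse to a handful).
#' @param pca_cap maximum retained components (default 50).
#' @param num_trees trees per forest.
#' @param rf_train_cap training rows per epoch; beyond it the lowest-error
#'   evaluations are kept (focuses the inverse map near the optimum).
#' @param min_node minimum terminal-node size of the forests.
#' @param sample_fraction per-tree subsample fraction (without replacement).
#' @param seed integer seed.
#' @return a `derf_config` list.
#' @export
derf_config <- function(pop_size = 200, f_range = c(0.2, 1),
                        bounds = c(0.066, 1.906), budget = 5000,
                        pop_cap = 400, rf_period = 500, rf_count = 10,
                        pca_target = 0.40, pca_min = 24, pca_cap = 50,
                        num_trees = 100, rf_train_cap = 1000, min_node = 5,
                        sample_fraction = 0.632, seed = 1) {
  stopifnot(pop_size >= 4, length(f_range) == 2, all(f_range > 0),
            length(bounds) == 2, bounds[1] < bounds[2], budget >= 1,
            pop_cap >= pop_size, rf_period >= 1, rf_count >= 1,
            pca_target > 0, pca_target <= 1, pca_cap >= 1,
            pca_min >= 1, pca_min <= pca_cap)
  structure(list(pop_size = pop_size, f_range = f_range, bounds = bounds,
                 budget = budget, pop_cap = pop_cap, rf_period = rf_period,
                 rf_count = rf_count, pca_target = pca_target,
                 pca_min = pca_min, pca_cap = pca_cap, num_trees = num_trees,
                 rf_train_cap = rf_train_cap, min_node = min_node,
                 sample_fraction = sample_fraction, seed = seed),
            class = "derf_config")
}

new_individual <- function(x, tag) {
  list(x = x, error = NA_real_, phenotype = NULL, tag = tag)
}

clamp_bounds <- function(x, bounds) pmin(pmax(x, bounds[1]), bounds[2])

#' Initialize the DE population
#'
#' Coordinates are drawn log-uniformly over the bounds; individuals are
#' tagged `init` and unevaluated.
#'
#' @param config a [derf_config].
#' @param n_dim number of unknown parameters, or a character vector of their
#'   names.
#' @param seed integer seed (defaults to the config seed).
#' @return list of individuals.
#' @export
init_population <- function(config, n_dim, seed = config$seed) {
  nms <- NULL
  if (is.character(n_dim)) { nms <- n_dim; n_dim <- length(n_dim) }
  set.seed(derive_seed(seed, "init"))
  lb <- log(config$bounds)
  lapply(seq_len(config$pop_size), function(i) {
    x <- exp(stats::runif(n_dim, lb[1], lb[2]))
    names(x) <- nms
    new_individual(x, "init")
  })
}

#' DE mutation proposal
#'
#' Draws three distinct evaluated individuals, orders the difference pair so
#' the lower-error one is `x_q` (ties broken by draw order), draws
#' `F ~ U(f_range)`, and returns `x_p + F (x_q - x_r)` clamped to the bounds.
#'
#' @param pop list of evaluated individuals.
#' @param config a [derf_config].
#' @param F optional fixed scale factor (draws from `f_range` if `NULL`).
#' @return an unevaluated individual tagged `de`.
#' @export
de_propose <- function(pop, config, F = NULL) {
  ev <- Filter(function(ind) is.finite(ind$error), pop)
  if (length(ev) < 3)
    stop("contract error: DE mutation needs at least 3 evaluated individuals")
  idx <- sample.int(length(ev), 3)
  p <- ev[[idx[1]]]; q <- ev[[idx[2]]]; r <- ev[[idx[3]]]
  if (r$error < q$error) { tmp <- q; q <- r; r <- tmp }
  if (is.null(F)) F <- stats::runif(1, config$f_range[1], config$f_range[2])
  x <- clamp_bounds(p$x + F * (q$x - r$x), config$bounds)
  new_individual(x, "de")
}

# normalize eval_fn output to list(error, phenotype)
eval_candidate <- function(eval_fn, x) {
  out <- tryCatch(eval_fn(x), error = function(e) e)
  if (inherits(out, "error"))
    return(list(error = NA_real_, phenotype = NULL,
                cause = conditionMessage(out)))
  if (is.list(out)) list(error = as.numeric(out$error),
                         phenotype = out$phenotype, cause = NULL)
  else list(error = as.numeric(out), phenotype = NULL, cause = NULL)
}

#' Median-threshold acceptance
#'
#' Evaluates the candidate once and inserts it iff its error is strictly
#' below the median error of the current population; beyond the population
#' cap the worst-error member (ties: oldest) is evicted.
#'
#' @param pop list of evaluated individuals.
#' @param candidate an unevaluated individual.
#' @param eval_fn evaluation function (fold-change vector to error, or to
#'   `list(error, phenotype)`).
#' @param config a [derf_config].
#' @return list with elements `pop`, `candidate` (evaluated), `accepted`,
#'   `median_before`, `cause` (non-`NULL` on evaluation failure).
#' @export
accept_candidate <- function(pop, candidate, eval_fn, config) {
  errs <- vapply(pop, function(i) i$error, 0.0)
  med <- stats::median(errs)
  ev <- eval_candidate(eval_fn, candidate$x)
  candidate$error <- ev$error
  candidate$phenotype <- ev$phenotype
  accepted <- FALSE
  if (is.null(ev$cause) && is.finite(candidate$error) &&
      candidate$error < med) {
    accepted <- TRUE
    pop <- c(pop, list(candidate))
    if (length(pop) > config$pop_cap) {
      errs2 <- vapply(pop, function(i) i$error, 0.0)
      pop[[which.max(errs2)]] <- NULL   # which.max: first (oldest) of ties
    }
  }
  list(pop = pop, candidate = candidate, accepted = accepted,
       median_before = med, cause = ev$cause)
}

#' Fit the principal-component feature basis
#'
#' Centers the phenotype rows and retains leading principal axes until the
#' cumulative explained variance reaches the target (or the component cap is
#' hit, flagged).
#'
#' @param phenotypes rows-of-measurements matrix (>= 2 rows).
#' @param config a [derf_config].
#' @return a `feature_basis` list: `center`, `rotation` (orthonormal axes in
#'   columns), `explained` (per-axis fractions), `k` (retained count),
#'   `capped`.
#' @export
fit_feature_basis <- function(phenotypes, config = derf_config()) {
  phenotypes <- as.matrix(phenotypes)
  stopifnot(nrow(phenotypes) >= 2)
  keep <- which(apply(phenotypes, 2, function(c) stats::var(c) > 0))
  if (!length(keep)) stop("degenerate basis: all phenotype columns constant")
  # correlation-scale PCA: measurement classes live on wildly different
  # scales, and unscaled axes would be dominated by the largest counts
  pc <- stats::prcomp(phenotypes[, keep, drop = FALSE], center = TRUE,
                      scale. = TRUE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(which(cumsum(frac) >= config$pca_target - 1e-12))
  capped <- k > config$pca_cap
  k <- max(k, min(config$pca_min %||% 1, length(frac)))
  k <- min(k, config$pca_cap, length(frac))
  structure(list(center = pc$center, scale = pc$scale,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 columns = keep, explained = frac[seq_len(k)], k = k,
                 capped = capped),
            class = "feature_basis")
}

#' Project phenotype rows onto a feature basis
#' @param basis a `feature_basis`.
#' @param phenotypes rows-of-measurements matrix (or one row).
#' @return rows-of-components matrix.
#' @export
project_features <- function(basis, phenotypes) {
  phenotypes <- rbind(phenotypes)
  z <- sweep(phenotypes[, basis$columns, drop = FALSE], 2, basis$center)
  z <- sweep(z, 2, basis$scale, "/")
  z %*% basis$rotation
}

#' Train one regression forest per unknown parameter
#'
#' @param features reduced phenotype rows (from [project_features()]).
#' @param targets matrix of fold-change values, one column per unknown name.
#' @param config a [derf_config].
#' @return an `rf_ensemble` list: per-name `ranger` forests, training size,
#'   out-of-bag R^2 and MSE per name.
#' @export
train_rf <- function(features, targets, config = derf_config()) {
  features <- as.matrix(features); targets <- as.matrix(targets)
  if (nrow(features) < 10)
    stop("contract error: random-forest training needs >= 10 rows")
  stopifnot(nrow(features) == nrow(targets))
  df <- as.data.frame(features)
  names(df) <- paste0("pc", seq_len(ncol(df)))
  forests <- lapply(seq_len(ncol(targets)), function(j) {
    d <- df; d$y <- targets[, j]
    ranger::ranger(y ~ ., data = d, num.trees = config$num_trees,
                   num.threads = 1,
                   min.node.size = config$min_node %||% 5,
                   replace = FALSE,
                   sample.fraction = config$sample_fraction %||% 0.632,
                   seed = derive_seed(config$seed, paste0("rf", j)))
  })
  names(forests) <- colnames(targets)
  structure(list(forests = forests, n_train = nrow(features),
                 oob_r2 = vapply(forests, function(f) f$r.squared, 0.0),
                 oob_mse = vapply(forests, function(f) f$prediction.error, 0.0)),
            class = "rf_ensemble")
}

#' Random-forest inverse proposal
#'
#' Starting from the best (lowest-error) individual, replaces each
#' coordinate, in a fixed name order, with the corresponding forest's
#' prediction at the target phenotype — the observed measurement vector the
#' search is trying to match (surrogate inversion). Without a target, the
#' best individual's own phenotype is used. Predictions are clamped to the
#' bounds.
#'
#' @param state an `rf_ensemble` from [train_rf()].
#' @param pop list of evaluated individuals.
#' @param basis the `feature_basis` the forests were trained under.
#' @param config a [derf_config].
#' @param target_phenotype measurement vector at which to invert (e.g. the
#'   mutant bundle means); `NULL` falls back to the best individual's
#'   phenotype.
#' @return an unevaluated individual tagged `rf`.
#' @export
rf_propose <- function(state, pop, basis, config = derf_config(),
                       target_phenotype = NULL) {
  if (!inherits(state, "rf_ensemble"))
    stop("contract error: rf_propose needs a trained rf_ensemble")
  errs <- vapply(pop, function(i) i$error, 0.0)
  best <- pop[[which.min(errs)]]
  phen <- target_phenotype %||% best$phenotype
  if (is.null(phen))
    stop("contract error: best individual carries no phenotype")
  feat <- project_features(basis, phen)
  df <- as.data.frame(feat)
  names(df) <- paste0("pc", seq_len(ncol(df)))
  x <- best$x
  for (nm in names(state$forests)) {
    pr <- stats::predict(state$forests[[nm]], data = df)$predictions
    x[nm] <- clamp_bounds(pr, config$bounds)
  }
  new_individual(x, "rf")
}

#' Run the hybrid DE-RF estimator
#'
#' Evaluates the initial population, then alternates DE proposals with
#' periodic random-forest injection epochs (every `rf_period` evaluations,
#' provided the evaluated candidates carry phenotype vectors), stopping at
#' the evaluation budget.
#'
#' @param eval_fn maps a fold-change vector to a prediction error, or to
#'   `list(error = , phenotype = )`; phenotypes enable the RF epochs.
#' @param config a [derf_config].
#' @param n_dim dimensionality, or a character vector of unknown names.
#' @param target_phenotype observed measurement vector the search should
#'   match; enables true surrogate inversion in the RF epochs.
#' @param keep_rejected keep rejected candidates' phenotypes in the RF
#'   training archive (default TRUE).
#' @return list with `best` (best-ever individual), `pop` (final
#'   population), `trace` (per-evaluation data frame: `eval`, `error`,
#'   `provenance`, `median_before`, `accepted`, `best_so_far`) and
#'   `archive` (all evaluated fold vectors and errors).
#' @export
run_derf <- function(eval_fn, config = derf_config(), n_dim,
                     target_phenotype = NULL, keep_rejected = TRUE) {
  if (config$budget < config$pop_size)
    stop("partial result: budget smaller than the initial population")
  pop <- init_population(config, n_dim)
  d <- length(pop[[1]]$x)
  nms <- names(pop[[1]]$x) %||% paste0("v", seq_len(d))
  for (i in seq_along(pop)) names(pop[[i]]$x) <- nms

  arch_x <- matrix(NA_real_, config$budget, d, dimnames = list(NULL, nms))
  arch_err <- rep(NA_real_, config$budget)
  arch_phen <- NULL
  trace <- data.frame(eval = seq_len(config$budget), error = NA_real_,
                      provenance = NA_character_, median_before = NA_real_,
                      accepted = NA, best_so_far = NA_real_)
  n_eval <- 0L
  best <- NULL
  record <- function(ind, med, acc) {
    n_eval <<- n_eval + 1L
    arch_x[n_eval, ] <<- ind$x
    arch_err[n_eval] <<- ind$error
    if (!is.null(ind$phenotype)) {
      if (is.null(arch_phen))
        arch_phen <<- matrix(NA_real_, config$budget, length(ind$phenotype))
      arch_phen[n_eval, ] <<- ind$phenotype
    }
    trace$error[n_eval] <<- ind$error
    trace$provenance[n_eval] <<- ind$tag
    trace$median_before[n_eval] <<- med
    trace$accepted[n_eval] <<- acc
    if (is.finite(ind$error) && (is.null(best) || ind$error < best$error))
      best <<- ind
    trace$best_so_far[n_eval] <<- if (is.null(best)) NA_real_ else best$error
  }

  # initial population: every member is evaluated and kept
  for (i in seq_along(pop)) {
    ev <- eval_candidate(eval_fn, pop[[i]]$x)
    pop[[i]]$error <- ev$error
    pop[[i]]$phenotype <- ev$phenotype
    record(pop[[i]], NA_real_, NA)
    if (n_eval >= config$budget) break
  }
  pop <- Filter(function(ind) is.finite(ind$error), pop)

  set.seed(derive_seed(config$seed, "main"))
  next_rf <- config$rf_period
  while (n_eval < config$budget) {
    use_rf <- n_eval >= next_rf && !is.null(arch_phen)
    if (use_rf) {
      next_rf <- next_rf + config$rf_period
      rows <- which(!is.na(arch_err[seq_len(n_eval)]) &
                      is.finite(arch_err[seq_len(n_eval)]))
      if (!keep_rejected) rows <- rows   # archive already holds evaluations
      ok <- rows[stats::complete.cases(arch_phen[rows, , drop = FALSE])]
      cap_n <- config$rf_train_cap %||% Inf
      if (length(ok) > cap_n)
        ok <- ok[order(arch_err[ok])[seq_len(cap_n)]]
      if (length(ok) >= 10) {
        basis <- tryCatch(
          fit_feature_basis(arch_phen[ok, , drop = FALSE], config),
          error = function(e) NULL)
        if (!is.null(basis)) {
          feats <- project_features(basis, arch_phen[ok, , drop = FALSE])
          state <- train_rf(feats, arch_x[ok, , drop = FALSE], config)
          for (j in seq_len(config$rf_count)) {
            if (n_eval >= config$budget || length(pop) < 1) break
            cand <- rf_propose(state, pop, basis, config, target_phenotype)
            res <- accept_candidate(pop, cand, eval_fn, config)
            pop <- res$pop
            record(res$candidate, res$median_before, res$accepted)
          }
        }
      }
      next
    }
    if (length(pop) < 3) stop("population collapsed below 3 individuals")
    cand <- de_propose(pop, config)
    res <- accept_candidate(pop, cand, eval_fn, config)
    pop <- res$pop
    record(res$candidate, res$median_before, res$accepted)
  }

  list(best = best, pop = pop, trace = trace[seq_len(n_eval), ],
       archive = list(x = arch_x[seq_len(n_eval), , drop = FALSE],
                      error = arch_err[seq_len(n_eval)]))
}

#' Prediction-error evaluation function for a challenge package
#'
#' Returns a closure mapping a fold-change vector over the unknown names to
#' the prediction error against the mutant bundle, together with the
#' predicted phenotype vector (enabling the RF epochs). Candidates that fail
#' to divide receive a large graded penalty (decreasing as the cell gets
#' closer to doubling) and a censored phenotype.
#'
#' @param pkg a `challenge_package`.
#' @param mode simulation mode for candidate predictions.
#' @param n_cells cells per evaluation in stochastic mode.
#' @param seed integer seed for stochastic evaluations.
#' @return function suitable for [run_derf()].
#' @export
make_challenge_eval <- function(pkg, mode = "deterministic", n_cells = 2,
                                seed = 1) {
  spec <- pkg$spec
  registry <- pkg$mutant_bundle$registry
  wt <- pkg$wildtype
  iu <- match(pkg$unknowns$name, wt$name)
  bp <- wt$class[iu] == "binding_probability"
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  function(fold) {
    params <- wt
    v <- wt$value[iu] * fold[pkg$unknowns$name]
    v[bp] <- pmin(v[bp], 1)
    params$value[iu] <- v
    if (mode == "deterministic") {
      traj <- simulate_cell(spec, params, mode = "deterministic")
      phen <- cell_measurements(spec, traj, registry, stochastic = FALSE)
      if (!traj$divided) {
        phen[is.na(phen)] <- spec$constants$max_time
        deficit <- 2 * spec$constants$initial_mass /
          traj$mass[length(traj$mass)]
        return(list(error = 1e7 * deficit, phenotype = phen))
      }
      err <- prediction_error(phen, pkg$mutant_bundle$mean,
                              pkg$mutant_bundle$var)
      list(error = as.numeric(err), phenotype = phen)
    } else {
      counter$n <- counter$n + 1L
      b <- simulate_population(spec, params, max(2, n_cells),
                               seed = derive_seed(seed, counter$n))
      phen <- b$mean
      bad <- !is.finite(phen)
      if (any(bad)) phen[bad] <- spec$constants$max_time
      err <- prediction_error(phen, pkg$mutant_bundle$mean,
                              pkg$mutant_bundle$var)
      list(error = as.numeric(err) * (1 + 100 * b$n_undivided),
           phenotype = phen)
    }
  }
}
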