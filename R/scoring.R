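# Challenge scoring: log-ratio parameter error, variance-weighted least
# squares prediction error, empirical meta-vector p-values, combined score,
# and the submission analytics (per-parameter errors, coefficients of
# variation, parameter/prediction-error correlations).

#' Log-ratio parameter error
#'
#' `e_param = (1/N) * sum((log10(v_est / v_true))^2)` over the N unknown
#' parameters.
#'
#' @param est named vector (or [param_set]) of estimated values over the
#'   unknown names.
#' @param truth named vector (or [param_set]) of true values over the same
#'   names.
#' @return the mean squared log10 ratio, with attribute `per_name` giving
#'   each parameter's contribution.
#' @export
param_error <- function(est, truth) {
  est <- as_named_values(est)
  truth <- as_named_values(truth)
  if (!setequal(names(est), names(truth)) ||
      length(est) != length(truth))
    stop("contract error: estimate and truth name sets differ")
  truth <- truth[names(est)]
  if (any(est <= 0) || any(truth <= 0))
    stop("domain error: parameter values must be positive")
  per <- (log10(est / truth))^2
  structure(mean(per), per_name = per)
}

as_named_values <- function(x) {
  if (inherits(x, "param_set") || (is.data.frame(x) && "value" %in% names(x)))
    return(stats::setNames(x$value, x$name))
  stopifnot(is.numeric(x), !is.null(names(x)))
  x
}

#' Variance-weighted least-squares prediction error
#'
#' `e_predict = (1/M) * sum(((v_true - v_est) / sigma_true)^2)` over the M
#' measurements whose true variance exceeds `var_floor`; measurements at or
#' below the floor (or with missing values) are excluded and counted.
#'
#' @param est_means estimated (predicted) measurement means.
#' @param true_means true measurement means.
#' @param true_vars true measurement variances (`sigma_true^2`).
#' @param var_floor exclusion floor on the variance (default `1e-12`).
#' @return the error, with attributes `n_used` and `n_excluded`.
#' @export
prediction_error <- function(est_means, true_means, true_vars,
                             var_floor = 1e-12) {
  stopifnot(length(est_means) == length(true_means),
            length(true_means) == length(true_vars))
  if (any(true_vars < 0, na.rm = TRUE)) stop("variances must be >= 0")
  ok <- is.finite(est_means) & is.finite(true_means) & is.finite(true_vars) &
    true_vars > var_floor
  if (!any(ok)) stop("undefined error: all measurements excluded")
  z2 <- (true_means[ok] - est_means[ok])^2 / true_vars[ok]
  structure(mean(z2), n_used = sum(ok), n_excluded = sum(!ok))
}

#' Empirical meta-vector p-value
#'
#' Builds `n_meta` meta vectors by sampling each coordinate independently and
#' uniformly from the pooled submissions' values at that coordinate, computes
#' their errors with `error_fn`, and returns the add-one-smoothed empirical
#' p-value `(1 + #\{meta error <= observed\}) / (n_meta + 1)`.
#'
#' @param observed_error the submission's error.
#' @param pool matrix of pooled submission vectors (rows = submissions,
#'   columns = coordinates).
#' @param error_fn function mapping one vector to its error.
#' @param n_meta number of meta vectors (default 10000).
#' @param seed integer seed.
#' @param joint if `TRUE`, resample whole rows instead of independent
#'   coordinates.
#' @return p-value in (0, 1]; a degenerate pool (all rows identical) returns
#'   1 with attribute `degenerate = TRUE`.
#' @export
empirical_pvalue <- function(observed_error, pool, error_fn, n_meta = 10000,
                             seed = 1, joint = FALSE) {
  pool <- as.matrix(pool)
  stopifnot(nrow(pool) >= 2, n_meta >= 1)
  if (all(apply(pool, 2, function(col) length(unique(col)) == 1)))
    return(structure(1, degenerate = TRUE))
  set.seed(as.integer(seed %% 2147483647))
  errs <- vapply(seq_len(n_meta), function(i) {
    v <- if (joint) pool[sample.int(nrow(pool), 1), ]
    else pool[cbind(sample.int(nrow(pool), ncol(pool), replace = TRUE),
                    seq_len(ncol(pool)))]
    as.numeric(error_fn(v))
  }, 0.0)
  (1 + sum(errs <= observed_error)) / (n_meta + 1)
}

#' Combined challenge score
#'
#' `s = -ln(p_param * p_predict)`.
#'
#' @param p_param,p_predict p-values in (0, 1].
#' @return the score (>= 0).
#' @export
overall_score <- function(p_param, p_predict) {
  if (p_param <= 0 || p_param > 1 || p_predict <= 0 || p_predict > 1)
    stop("domain error: p-values must lie in (0, 1]")
  -log(p_param * p_predict)
}

#' Per-parameter errors averaged over the top-scoring submissions
#'
#' Ranks submissions by their overall score (descending) and averages each
#' unknown parameter's squared log10 ratio across the top `top_k`.
#'
#' @param submissions list of submissions; each carries `values` (named
#'   vector) and `score`.
#' @param truth named vector of true values.
#' @param top_k number of top submissions to average (all, with a warning
#'   flag, if fewer are available).
#' @return named vector of mean per-parameter errors, with attribute
#'   `truncated` if fewer than `top_k` submissions were available.
#' @export
per_parameter_errors <- function(submissions, truth, top_k = 50) {
  truth <- as_named_values(truth)
  scores <- vapply(submissions, function(s) s$score, 0.0)
  truncated <- length(submissions) < top_k
  k <- min(top_k, length(submissions))
  top <- submissions[order(scores, decreasing = TRUE)[seq_len(k)]]
  per <- sapply(top, function(s) {
    v <- as_named_values(s$values)[names(truth)]
    (log10(v / truth))^2
  })
  structure(rowMeans(as.matrix(per)), truncated = truncated)
}

#' Coefficients of variation across cells
#'
#' Per measurement, the unbiased standard deviation across cells divided by
#' the absolute mean. Zero-mean measurements are flagged `NA` rather than
#' divided.
#'
#' @param cells cells x measurements matrix (e.g. the `cells` component of a
#'   [data_bundle]).
#' @return numeric vector of CVs (NA where the mean is zero or the
#'   measurement is missing).
#' @export
coefficient_of_variation <- function(cells) {
  cells <- as.matrix(cells)
  if (nrow(cells) < 2) stop("contract error: at least two cells required")
  mu <- colMeans(cells, na.rm = TRUE)
  sd <- apply(cells, 2, stats::sd, na.rm = TRUE)
  out <- ifelse(mu == 0, NA_real_, sd / abs(mu))
  out[is.nan(mu)] <- NA_real_
  out
}

#' Correlation of submitted parameter values with prediction error
#'
#' For each unknown parameter, the Spearman rank correlation between the
#' submitted value and the submission's prediction error across submissions.
#'
#' @param submissions list of submissions carrying `values` (named vector)
#'   and `e_predict`.
#' @return named vector of rank correlations (`NA` with a `constant`
#'   attribute entry where a column is constant).
#' @export
parameter_error_correlation <- function(submissions) {
  if (length(submissions) < 3)
    stop("contract error: at least three submissions required")
  ep <- vapply(submissions, function(s) s$e_predict, 0.0)
  vals <- do.call(rbind, lapply(submissions,
                                function(s) as_named_values(s$values)))
  out <- suppressWarnings(
    apply(vals, 2, function(col) {
      if (length(unique(col)) == 1 || length(unique(ep)) == 1) NA_real_
      else stats::cor(col, ep, method = "spearman")
    }))
  structure(out, constant = names(out)[is.na(out)])
}

# ---- submission plumbing -----------------------------------------------------

#' Score a submission against a challenge package
#'
#' Computes the parameter error against the sealed truth, simulates the
#' submission's predicted phenotype to compute the prediction error against
#' the mutant bundle, and (given a pool of submissions) the empirical
#' p-values and combined score.
#'
#' @param pkg a `challenge_package`.
#' @param values named vector of absolute estimated values over the unknown
#'   names.
#' @param pool optional list of submissions (each with `values` and
#'   `predictions`) for the empirical null; without it only the errors are
#'   returned.
#' @param n_cells cells used to simulate the submission's prediction vector.
#' @param mode simulation mode for predictions.
#' @param n_meta,seed empirical-null settings.
#' @return a `score_report` list: `e_param`, `e_predict`, `p_param`,
#'   `p_predict`, `s`, per-name errors, per-data-class decomposition and the
#'   predictions used.
#' @export
score_submission <- function(pkg, values, pool = NULL, n_cells = 4,
                             mode = "deterministic", n_meta = 10000,
                             seed = 1) {
  truth <- challenge_truth(pkg)$mutant
  tv <- param_values(truth)[pkg$unknowns$name]
  values <- as_named_values(values)
  if (!setequal(names(values), pkg$unknowns$name))
    stop("contract error: submission must cover exactly the unknown names; ",
         "missing: ", paste(setdiff(pkg$unknowns$name, names(values)),
                            collapse = ", "))
  ep <- param_error(values[pkg$unknowns$name], tv)
  pred <- predict_phenotype(pkg, values, n_cells = n_cells, mode = mode,
                            seed = seed)
  epr <- prediction_error(pred, pkg$mutant_bundle$mean, pkg$mutant_bundle$var)
  per_class <- tapply(seq_along(pred), pkg$mutant_bundle$registry$data_class,
                      function(i) {
                        tryCatch(as.numeric(
                          prediction_error(pred[i], pkg$mutant_bundle$mean[i],
                                           pkg$mutant_bundle$var[i])),
                          error = function(e) NA_real_)
                      })
  rep <- list(e_param = as.numeric(ep), e_predict = as.numeric(epr),
              per_name = attr(ep, "per_name"),
              per_class = per_class, predictions = pred,
              n_meta = n_meta, seed = seed)
  if (!is.null(pool)) {
    pmat <- t(sapply(pool, function(s) as_named_values(s$values)[names(values)]))
    rep$p_param <- empirical_pvalue(rep$e_param, pmat,
                                    function(v) param_error(
                                      stats::setNames(v, colnames(pmat)), tv),
                                    n_meta = n_meta, seed = seed)
    prmat <- t(sapply(pool, function(s) s$predictions))
    rep$p_predict <- empirical_pvalue(
      rep$e_predict, prmat,
      function(v) prediction_error(v, pkg$mutant_bundle$mean,
                                   pkg$mutant_bundle$var),
      n_meta = n_meta, seed = seed + 1)
    rep$s <- overall_score(as.numeric(rep$p_param), as.numeric(rep$p_predict))
  }
  class(rep) <- "score_report"
  rep
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> e_param = %.4g, e_predict = %.4g%s\n",
              x$e_param, x$e_predict,
              if (!is.null(x[["s"]])) sprintf(", s = %.3f", x[["s"]]) else ""))
  invisible(x)
}

#' Predicted measurement means for a candidate parameter estimate
#'
#' Applies the estimated unknown values on top of the disclosed wild type and
#' simulates the surrogate to produce a full predicted measurement vector.
#'
#' @param pkg a `challenge_package`.
#' @param values named vector over (a subset of) the unknown names.
#' @param n_cells cells to average over in stochastic mode.
#' @param mode simulation mode.
#' @param seed integer seed.
#' @return numeric vector over the bundle measurement index (NA where the
#'   candidate failed to divide).
#' @export
predict_phenotype <- function(pkg, values, n_cells = 4,
                              mode = "deterministic", seed = 1) {
  params <- pkg$wildtype
  i <- match(names(values), params$name)
  stopifnot(!anyNA(i))
  params$value[i] <- pmin(values,
                          ifelse(params$class[i] == "binding_probability", 1, Inf))
  if (mode == "deterministic") {
    traj <- simulate_cell(pkg$spec, params, mode = "deterministic")
    cell_measurements(pkg$spec, traj, pkg$mutant_bundle$registry,
                      stochastic = FALSE)
  } else {
    b <- simulate_population(pkg$spec, params, max(2, n_cells), seed = seed)
    b$mean
  }
}

#' Read and write submissions, and batch-score a directory
#'
#' A submission TSV has columns `name` and `value`.
#'
#' @param values named vector of estimates.
#' @param path TSV path.
#' @return `read_submission` returns a named vector.
#' @export
write_submission <- function(values, path) {
  utils::write.table(data.frame(name = names(values), value = unname(values)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_submission
#' @export
read_submission <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stats::setNames(x$value, x$name)
}

#' Synthesize a pool of noisy submissions (for analytics and nulls)
#'
#' Draws submissions log-normally around the sealed truth with a given
#' log10 spread, simulating the population of entries a challenge would
#' receive.
#'
#' @param pkg a `challenge_package`.
#' @param n number of submissions.
#' @param spread standard deviation of the log10 perturbation.
#' @param seed integer seed.
#' @param mode prediction simulation mode.
#' @return list of submissions with `values`, `predictions`, `e_param`,
#'   `e_predict`.
#' @export
synthesize_submissions <- function(pkg, n = 20, spread = 0.3, seed = 1,
                                   mode = "deterministic") {
  truth <- param_values(challenge_truth(pkg)$mutant)[pkg$unknowns$name]
  lapply(seq_len(n), function(i) {
    set.seed(derive_seed(seed, paste0("sub", i)))
    v <- truth * 10^stats::rnorm(length(truth), 0, spread)
    bp <- pkg$unknowns$class == "binding_probability"
    v[bp] <- pmin(v[bp], 1)
    pred <- predict_phenotype(pkg, v, mode = mode, seed = derive_seed(seed, i))
    list(values = v, predictions = pred,
         e_param = as.numeric(param_error(v, truth)),
         e_predict = as.numeric(
           prediction_error(pred, pkg$mutant_bundle$mean,
                            pkg$mutant_bundle$var)))
  })
}
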