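# Challenge construction: sensitivity-weighted mutant building, unknown-set
# selection, perturbation library, and budgeted data release.

#' Sensitivity of the doubling time to one parameter
#'
#' Central finite difference of `ln(doubling time)` with respect to
#' `ln(value)`. In stochastic mode each endpoint is averaged over `n_cells`
#' replicate cells using common random seeds across the two endpoints
#' (variance reduction).
#'
#' @param spec a [cell_model_spec].
#' @param params a [param_set].
#' @param name parameter to perturb.
#' @param n_cells replicate cells per endpoint (stochastic mode).
#' @param rel_step relative step, in (0, 0.5]; the log step is
#'   `log(1 + rel_step)`.
#' @param seed integer seed for the replicate streams.
#' @param mode `"stochastic"` or `"deterministic"`.
#' @return the dimensionless elasticity `d ln T / d ln v`.
#' @export
estimate_sensitivity <- function(spec, params, name, n_cells = 8,
                                 rel_step = 0.1, seed = 1,
                                 mode = c("stochastic", "deterministic")) {
  mode <- match.arg(mode)
  stopifnot(name %in% params$name, rel_step > 0, rel_step <= 0.5)
  h <- log(1 + rel_step)
  endpoint <- function(s, lab) {
    p <- params
    p$value[p$name == name] <- p$value[p$name == name] * exp(s)
    bp <- p$class == "binding_probability"
    p$value[bp] <- pmin(p$value[bp], 1)
    if (mode == "deterministic") {
      tr <- simulate_cell(spec, p, mode = "deterministic")
      if (!tr$divided)
        stop(sprintf("sensitivity undefined: %s endpoint failed to divide", lab))
      return(tr$events$t_cytokinesis)
    }
    tt <- vapply(seq_len(n_cells), function(j) {
      tr <- simulate_cell(spec, p, seed = derive_seed(seed, paste0("sens", j)),
                          mode = "stochastic")
      if (tr$divided) tr$events$t_cytokinesis else NA_real_
    }, 0.0)
    if (all(is.na(tt)))
      stop(sprintf("sensitivity undefined: %s endpoint failed to divide", lab))
    mean(tt, na.rm = TRUE)
  }
  (log(endpoint(h, "upper")) - log(endpoint(-h, "lower"))) / (2 * h)
}

#' Plan one mutant-construction step
#'
#' Converts per-parameter sensitivities into the fold changes required to
#' increase the doubling time by `per_step_increase`: the required log fold
#' change is `log(1 + per_step_increase) / sensitivity`, clipped to
#' `max_log_fold` in magnitude. Parameters whose sensitivity magnitude falls
#' below `floor` are excluded (their planned changes would be astronomically
#' large).
#'
#' @param sensitivities named numeric vector of elasticities.
#' @param per_step_increase target fractional doubling-time increase (> 0).
#' @param floor sensitivity-magnitude floor.
#' @param max_log_fold clip on the planned |log fold change|.
#' @return named vector of fold changes for the eligible parameters.
#' @export
plan_step <- function(sensitivities, per_step_increase, floor = 1e-3,
                      max_log_fold = 2.5) {
  stopifnot(per_step_increase > 0)
  s <- sensitivities[abs(sensitivities) >= floor]
  if (!length(s)) stop("no candidate: all sensitivities are below the floor")
  lf <- log(1 + per_step_increase) / s
  lf <- pmin(pmax(lf, -max_log_fold), max_log_fold)
  exp(lf)
}

#' Build the slow-growing mutant strain
#'
#' Iterates `n_steps` times: recompute the sensitivity of the doubling time to
#' every not-yet-modified parameter, plan the fold changes that would each
#' raise the doubling time by `per_step_increase`, draw one parameter with
#' probability proportional to its planned |log fold change| (or inversely,
#' see `weighting`), apply the change, and log the achieved doubling time.
#' Construction stops early (flagged) if the doubling-time ratio already
#' exceeds the compounded target `(1 + per_step_increase)^n_steps`.
#'
#' @param spec a [cell_model_spec].
#' @param wildtype the wild-type [param_set].
#' @param n_steps number of parameters to modify (default 15).
#' @param per_step_increase per-step doubling-time increase (default 1.9%,
#'   compounding to a 33% increase over 15 steps).
#' @param seed integer seed governing the weighted selections and the
#'   stochastic doubling-time measurements.
#' @param mode mode in which the achieved doubling time is measured.
#' @param sens_mode mode in which step sensitivities are computed
#'   (deterministic by default: exact, fast, stable weights).
#' @param n_cells_sens,n_cells_log replicate cells for stochastic
#'   sensitivities and doubling-time logging.
#' @param weighting `"fold"` (probability proportional to |log fold change|)
#'   or `"inverse_fold"`.
#' @return an object of class `mutant_strain`: the mutant [param_set], the
#'   modification table, the per-step log and the achieved ratio.
#' @export
build_mutant <- function(spec, wildtype = spec$wildtype, n_steps = 15,
                         per_step_increase = 0.019, seed = 1,
                         mode = c("stochastic", "deterministic"),
                         sens_mode = "deterministic",
                         n_cells_sens = 8, n_cells_log = 16,
                         weighting = c("fold", "inverse_fold")) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  stopifnot(n_steps >= 0, n_steps <= nrow(wildtype))
  target <- (1 + per_step_increase)^n_steps

  measure_T <- function(params, tag) {
    if (mode == "deterministic")
      return(doubling_time(simulate_cell(spec, params, mode = "deterministic")))
    trs <- lapply(seq_len(n_cells_log), function(j)
      simulate_cell(spec, params, mode = "stochastic",
                    seed = derive_seed(seed, paste0(tag, "T", j))))
    suppressWarnings(as.numeric(doubling_time(trs)))
  }

  T0 <- measure_T(wildtype, "wt")
  params <- wildtype
  modified <- character(0)
  step_log <- list()
  early <- FALSE

  for (step in seq_len(n_steps)) {
    ratio_now <- if (length(step_log))
      step_log[[length(step_log)]]$achieved_ratio else 1
    if (ratio_now >= target) { early <- TRUE; break }
    eligible <- setdiff(params$name, modified)
    if (!length(eligible)) stop("construction error: eligible pool exhausted")
    sens <- vapply(eligible, function(nm)
      tryCatch(estimate_sensitivity(spec, params, nm, n_cells = n_cells_sens,
                                    seed = derive_seed(seed, paste0("s", step)),
                                    mode = sens_mode),
               error = function(e) NA_real_), 0.0)
    sens <- sens[is.finite(sens)]
    folds <- plan_step(sens, per_step_increase)
    w <- abs(log(folds))
    if (weighting == "inverse_fold") w <- 1 / w
    set.seed(derive_seed(seed, paste0("pick", step)))
    chosen <- sample(names(folds), 1, prob = w)
    wt_val <- params$value[params$name == chosen]
    params <- apply_folds(params, stats::setNames(folds[chosen], chosen))
    mut_val <- params$value[params$name == chosen]
    modified <- c(modified, chosen)
    Tk <- measure_T(params, paste0("step", step))
    step_log[[step]] <- list(step = step, chosen = chosen,
                             planned_fold = unname(folds[chosen]),
                             applied_fold = mut_val / wt_val,
                             n_eligible = length(folds),
                             weights = w,
                             achieved_T = Tk, achieved_ratio = Tk / T0)
  }

  mods <- data.frame(
    name = modified,
    wildtype = wildtype$value[match(modified, wildtype$name)],
    mutant = params$value[match(modified, params$name)],
    stringsAsFactors = FALSE)
  mods$fold <- mods$mutant / mods$wildtype
  structure(list(mutant = params, wildtype = wildtype, modifications = mods,
                 step_log = step_log,
                 doubling_time_wt = T0,
                 achieved_ratio = if (length(step_log))
                   step_log[[length(step_log)]]$achieved_ratio else 1,
                 early_termination = early, seed = seed, mode = mode),
            class = "mutant_strain")
}

#' @export
print.mutant_strain <- function(x, ...) {
  cat(sprintf("<mutant_strain> %d modified parameters, doubling-time ratio %.3f%s\n",
              nrow(x$modifications), x$achieved_ratio,
              if (x$early_termination) " (early termination)" else ""))
  invisible(x)
}

#' Select the unknown-parameter set
#'
#' The unknown set released to estimators is the modified names plus
#' `n_extra` unmodified names sampled to match the modified class proportions
#' (largest-remainder rounding). When a class pool cannot supply its target,
#' the shortfall is redistributed to classes with remaining names (flagged).
#'
#' @param strain a `mutant_strain`.
#' @param wildtype the wild-type [param_set].
#' @param n_extra number of unmodified decoys (default 15, for 30 unknowns).
#' @param seed integer seed.
#' @return an object of class `unknown_set`: a data frame `name`, `class`;
#'   the modified/unmodified truth flags are carried in a sealed attribute
#'   read only by scoring.
#' @export
select_unknowns <- function(strain, wildtype = strain$wildtype, n_extra = 15,
                            seed = 1) {
  mod <- strain$modifications$name
  mod_class <- wildtype$class[match(mod, wildtype$name)]
  pool <- wildtype[!(wildtype$name %in% mod), ]
  if (n_extra > nrow(pool))
    stop("selection error: unmodified pool smaller than n_extra")

  cnt <- tabulate(factor(mod_class, PARAM_CLASSES), 3)
  avail <- tabulate(factor(pool$class, PARAM_CLASSES), 3)
  quota <- largest_remainder(n_extra * cnt / sum(cnt), n_extra)
  # cap at pool and redistribute shortfall by largest remainder
  redistributed <- any(quota > avail)
  while (any(quota > avail)) {
    over <- which(quota > avail)
    short <- sum(quota[over] - avail[over])
    quota[over] <- avail[over]
    room <- avail - quota
    if (sum(room) < short)
      stop("selection error: class pools too small for ",
           paste(PARAM_CLASSES[over], collapse = ", "))
    add <- largest_remainder(short * room / sum(room), short)
    quota <- quota + pmin(add, room)
  }

  set.seed(derive_seed(seed, "unknowns"))
  extras <- unlist(lapply(seq_along(PARAM_CLASSES), function(k) {
    nm <- pool$name[pool$class == PARAM_CLASSES[k]]
    if (quota[k] == 0) character(0) else sample(nm, quota[k])
  }))
  all_names <- c(mod, extras)
  out <- data.frame(name = all_names,
                    class = wildtype$class[match(all_names, wildtype$name)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$name), ]
  rownames(out) <- NULL
  class(out) <- c("unknown_set", "data.frame")
  attr(out, "sealed_modified") <- mod
  attr(out, "redistributed") <- redistributed
  out
}

largest_remainder <- function(x, total) {
  f <- floor(x)
  r <- total - sum(f)
  if (r > 0) {
    o <- order(x - f, decreasing = TRUE)
    f[o[seq_len(r)]] <- f[o[seq_len(r)]] + 1
  }
  as.integer(f)
}

#' Generate a complete challenge package
#'
#' Builds the mutant strain, its 32-cell data bundle, the 30-name unknown set
#' and the full perturbation library (2-fold up and down perturbations of
#' every unknown parameter, 8 cells per condition, eight data classes each),
#' and sets the perturbation request budget to 50 distinct
#' (condition, data-class) releases. All randomness derives from the master
#' seed.
#'
#' @param spec a [cell_model_spec].
#' @param seed master seed.
#' @param n_cells_mutant,n_cells_perturb population sizes (paper defaults
#'   32 and 8).
#' @param budget perturbation request budget (default 50).
#' @param ... passed to [build_mutant()].
#' @return an object of class `challenge_package`. The mutant truth is sealed
#'   behind [challenge_truth()], which only the scoring path may call.
#' @export
generate_challenge <- function(spec, seed = 1, n_cells_mutant = 32,
                               n_cells_perturb = 8, budget = 50, ...) {
  strain <- build_mutant(spec, seed = derive_seed(seed, "mutant"), ...)
  unknowns <- select_unknowns(strain, seed = derive_seed(seed, "select"))
  mutant_bundle <- simulate_population(spec, strain$mutant, n_cells_mutant,
                                       seed = derive_seed(seed, "mdata"))
  conditions <- expand.grid(name = unknowns$name, direction = c("up", "down"),
                            stringsAsFactors = FALSE)
  perturbations <- vector("list", nrow(conditions))
  names(perturbations) <- paste(conditions$name, conditions$direction, sep = "_")
  for (i in seq_len(nrow(conditions))) {
    fold <- if (conditions$direction[i] == "up") 2 else 0.5
    p <- apply_folds(strain$mutant,
                     stats::setNames(fold, conditions$name[i]))
    perturbations[[i]] <- simulate_population(
      spec, p, n_cells_perturb,
      seed = derive_seed(seed, names(perturbations)[i]))
  }
  ledger <- new.env(parent = emptyenv())
  ledger$budget <- as.integer(budget)
  ledger$released <- character(0)
  pkg <- structure(list(
    spec = spec, wildtype = strain$wildtype, mutant_bundle = mutant_bundle,
    unknowns = unknowns, perturbations = perturbations,
    conditions = conditions, ledger = ledger, master_seed = seed
  ), class = "challenge_package")
  attr(pkg, "sealed_truth") <- strain
  pkg
}

#' Number of perturbation data sets in a package
#'
#' One data set is one (perturbation condition, data class) pair.
#' @param pkg a `challenge_package`.
#' @return integer count.
#' @export
perturbation_dataset_count <- function(pkg) {
  length(pkg$perturbations) * length(DATA_CLASSES)
}

#' Number of mutant-strain data sets in a package (one per data class)
#' @param pkg a `challenge_package`.
#' @return integer count.
#' @export
mutant_dataset_count <- function(pkg) length(DATA_CLASSES)

#' Remaining perturbation request budget
#' @param pkg a `challenge_package`.
#' @return integer.
#' @export
remaining_budget <- function(pkg) pkg$ledger$budget

#' Sealed mutant truth (scoring only)
#'
#' Returns the mutant strain held back from estimators. Only the scoring and
#' analytics paths may call this; estimator code must never touch it.
#' @param pkg a `challenge_package`.
#' @return the `mutant_strain`.
#' @export
challenge_truth <- function(pkg) attr(pkg, "sealed_truth")

#' @export
print.challenge_package <- function(x, ...) {
  cat(sprintf(paste0("<challenge_package> %d unknowns, %d mutant data sets, ",
                     "%d perturbation data sets, budget %d\n"),
              nrow(x$unknowns), mutant_dataset_count(x),
              perturbation_dataset_count(x), remaining_budget(x)))
  invisible(x)
}

#' Request one perturbation data set
#'
#' Releases the measurements of one (condition, data class) pair and
#' decrements the budget. Repeated requests for an already-released data set
#' are free.
#'
#' @param pkg a `challenge_package`.
#' @param name unknown-parameter name of the condition.
#' @param direction `"up"` or `"down"` (2-fold).
#' @param data_class one of the eight data-class names.
#' @return data frame of measurements (as [bundle_slice()]).
#' @export
request_perturbation <- function(pkg, name, direction = c("up", "down"),
                                 data_class) {
  direction <- match.arg(direction)
  key <- paste(name, direction, sep = "_")
  if (!key %in% names(pkg$perturbations))
    stop("lookup error: no perturbation condition for parameter ", name)
  stopifnot(data_class %in% DATA_CLASSES)
  rel_key <- paste(key, data_class, sep = ":")
  if (!rel_key %in% pkg$ledger$released) {
    if (pkg$ledger$budget <= 0)
      stop("budget error: perturbation request budget exhausted")
    pkg$ledger$budget <- pkg$ledger$budget - 1L
    pkg$ledger$released <- c(pkg$ledger$released, rel_key)
  }
  bundle_slice(pkg$perturbations[[key]], data_class)
}
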