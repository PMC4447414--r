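# Reduced physical-model estimators: read parameters directly off the data
# bundles by inverting the surrogate's steady-state relations, then refine by
# matching predicted and observed phenotypes.
#
# binding probabilities: ChIP-seq counts corrected by the DNA-seq copy-number
#   gradient, calibrated on genes with known values (chip_g proportional to
#   p_g * copy_g);
# RNA half-lives: time-averaged birth-death balance, including the copy-number
#   step at fork passage (solved for the decay rate);
# turnover numbers: inversion of the saturable flux law
#   v = kcat * E * S / (K + S) from flux, enzyme and metabolite averages.

new_reduced_estimate <- function(name, class, estimate, se = NA_real_,
                                 method, flag = "") {
  x <- data.frame(name = name, class = class, estimate = estimate, se = se,
                  method = method, flag = flag, stringsAsFactors = FALSE)
  class(x) <- c("reduced_estimate", "data.frame")
  x
}

# copy number at a chromosome position, interpolated from the DNA-seq bins
copy_at <- function(bundle, position) {
  dna <- bundle_slice(bundle, "dnaseq")
  mids <- as.numeric(sub("bin_", "", dna$entity))
  d <- pmin(position, 1 - position)
  stats::approx(mids, dna$mean, xout = d, rule = 2)$y
}

#' Estimate promoter binding probabilities from ChIP-seq and DNA-seq
#'
#' Lifetime transcription-initiation counts scale as
#' `chip_g = p_g * k_txn * T * copy_g`, so after dividing by the copy number
#' interpolated from the DNA-seq gradient at each gene's position, a single
#' calibration constant (fit by least squares on the genes with known binding
#' probabilities) converts corrected counts to probabilities.
#'
#' @param bundle a [data_bundle].
#' @param spec the disclosed [cell_model_spec] structure.
#' @param targets names of the unknown binding-probability parameters.
#' @param calibration named vector of known binding probabilities
#'   (parameter names `p_<gene>`); may be empty only when
#'   `analytic_fallback` is allowed.
#' @param prob_floor positive floor for degenerate (zero-count) genes.
#' @param analytic_fallback when no calibration gene is available, derive the
#'   calibration constant from the disclosed model structure
#'   (`alpha = 1 / (k_txn * T)`) instead of erroring.
#' @return a `reduced_estimate` table (method `chip_copy`) with the fitted
#'   calibration constant in attribute `alpha`.
#' @export
estimate_bind_probs <- function(bundle, spec, targets, calibration = NULL,
                                prob_floor = 1e-6,
                                analytic_fallback = FALSE) {
  if (!length(calibration) && !analytic_fallback)
    stop("calibration error: no genes with known binding probabilities")
  chip <- bundle_slice(bundle, "chipseq")
  genes <- function(par) sub("^p_", "", par)
  pos <- spec$gene_positions[match(genes(c(names(calibration), targets)),
                                   spec$gene_names)]
  cn <- copy_at(bundle, pos)
  if (any(cn <= 0)) stop("data error: zero copy number")
  counts <- chip$mean[match(genes(c(names(calibration), targets)),
                            chip$entity)]
  x <- counts / cn
  ncal <- length(calibration)
  if (ncal > 0) {
    alpha <- sum(calibration * x[seq_len(ncal)]) / sum(x[seq_len(ncal)]^2)
    est <- alpha * x[-seq_len(ncal)]
    tcounts <- counts[-seq_len(ncal)]
  } else {
    alpha <- 1 / (spec$constants$k_txn * as.numeric(doubling_time(bundle)))
    est <- alpha * x
    tcounts <- counts
  }
  flag <- ifelse(tcounts <= 0, "inestimable: zero chip count", "")
  est <- pmin(pmax(est, prob_floor), 1)
  out <- new_reduced_estimate(targets, "binding_probability", est,
                              method = "chip_copy", flag = flag)
  attr(out, "alpha") <- alpha
  out
}

#' Estimate RNA half-lives from expression, ChIP-seq-derived synthesis and
#' the replication gradient
#'
#' In the surrogate, a gene's RNA sits at the birth-death steady state
#' `RNA = synth / lambda` before its locus is duplicated and relaxes toward
#' twice that level afterwards. The time-averaged abundance is therefore
#' `(p k_txn / lambda) * (cbar - (1 - exp(-lambda * Delta)) / (lambda * T))`
#' with `cbar` the gene's mean copy number, `Delta` the post-duplication
#' interval implied by it, and `T` the doubling time; the decay rate `lambda`
#' is solved from this relation and `t_half = ln 2 / lambda`.
#'
#' @param bundle a [data_bundle].
#' @param spec the disclosed [cell_model_spec] structure.
#' @param targets names of the unknown half-life parameters
#'   (`thalf_<gene>`).
#' @param bind_probs named vector of binding probabilities covering the
#'   target genes (known values plus [estimate_bind_probs()] output).
#' @return a `reduced_estimate` table (method `halflife_ss`).
#' @export
estimate_half_lives <- function(bundle, spec, targets, bind_probs) {
  rna <- bundle_slice(bundle, "rna_array")
  Tdiv <- as.numeric(doubling_time(bundle))
  k_txn <- spec$constants$k_txn
  genes <- sub("^thalf_", "", targets)
  pos <- spec$gene_positions[match(genes, spec$gene_names)]
  cbar <- copy_at(bundle, pos)
  rbar <- rna$mean[match(genes, rna$entity)]
  p <- bind_probs[paste0("p_", genes)]
  est <- rep(NA_real_, length(targets))
  flag <- rep("", length(targets))
  for (i in seq_along(targets)) {
    if (!is.finite(p[i]) || p[i] <= 0 || !is.finite(rbar[i]) || rbar[i] <= 0) {
      flag[i] <- "inestimable: zero synthesis or expression"
      est[i] <- 1e-6
      next
    }
    synth1 <- p[i] * k_txn               # single-copy synthesis rate
    delta <- max(0, (cbar[i] - 1)) * Tdiv  # post-duplication interval
    f <- function(lam)
      synth1 / lam * (cbar[i] - (1 - exp(-lam * delta)) / (lam * Tdiv)) - rbar[i]
    # f is decreasing in lambda; bracket on a wide log range
    lo <- 1e-4; hi <- 1e6
    if (f(lo) < 0) { est[i] <- log(2) / lo; flag[i] <- "at slow-decay bound"
    } else if (f(hi) > 0) { est[i] <- log(2) / hi; flag[i] <- "at fast-decay bound"
    } else {
      lam <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
      est[i] <- log(2) / lam
    }
  }
  new_reduced_estimate(targets, "rna_half_life", est,
                       method = "halflife_ss", flag = flag)
}

#' Estimate reaction turnover numbers by inverting the flux law
#'
#' `kcat_r = v_r / (E_r * S_r / (K + S_r))` using time-averaged fluxes,
#' enzyme abundances (protein array) and metabolite concentrations.
#'
#' @param bundle a [data_bundle].
#' @param spec the disclosed [cell_model_spec] structure.
#' @param targets names of the unknown turnover parameters (`kcat_<rxn>`).
#' @return a `reduced_estimate` table (method `kcat_flux`).
#' @export
estimate_kcats <- function(bundle, spec, targets) {
  fx <- bundle_slice(bundle, "reaction_fluxes")
  pr <- bundle_slice(bundle, "protein_array")
  met <- bundle_slice(bundle, "metabolite_concentrations")
  K <- spec$constants$K
  rxn <- sub("^kcat_", "", targets)
  ri <- match(rxn, spec$reaction_names)
  enz <- spec$gene_names[spec$metabolic_genes[ri]]
  v <- fx$mean[match(rxn, fx$entity)]
  E <- pr$mean[match(enz, pr$entity)]
  S <- met$mean[spec$met_of_reaction[ri]]
  sat <- S / (K + S)
  est <- v / (E * sat)
  flag <- ifelse(!is.finite(est) | E <= 0 | v <= 0,
                 "inestimable: zero enzyme or flux", "")
  est[!is.finite(est) | est <= 0] <- 1e-6
  new_reduced_estimate(targets, "turnover_number", est,
                       method = "kcat_flux", flag = flag)
}

#' Greedy coordinate refinement by phenotype matching
#'
#' Cyclic coordinate search: for each name in turn, evaluates a small
#' multiplicative step up and down and keeps the move iff the prediction
#' error decreases. The step factor shrinks by `shrink` after every full
#' cycle without improvement. The returned error never exceeds the initial
#' error.
#'
#' @param initial named vector of positive starting values covering the
#'   unknowns.
#' @param eval_fn maps a named value vector to a prediction error.
#' @param budget maximum number of evaluations (>= number of unknowns).
#' @param step initial multiplicative step (default 1.1).
#' @param shrink per-stale-cycle step shrink factor (default 0.5).
#' @return named vector of refined values with attributes `error`,
#'   `initial_error`, `n_eval`.
#' @export
refine_by_matching <- function(initial, eval_fn, budget = 300, step = 1.1,
                               shrink = 0.5) {
  stopifnot(budget >= length(initial), all(initial > 0))
  values <- initial
  safe_eval <- function(v) tryCatch(as.numeric(eval_fn(v)),
                                    error = function(e) NA_real_)
  err <- safe_eval(values)
  n_eval <- 1L
  if (!is.finite(err)) stop("refinement error: initial point not evaluable")
  err0 <- err
  repeat {
    improved <- FALSE
    for (nm in names(values)) {
      if (n_eval + 2 > budget) break
      for (f in c(step, 1 / step)) {
        cand <- values
        cand[nm] <- cand[nm] * f
        e <- safe_eval(cand)
        n_eval <- n_eval + 1L
        if (is.finite(e) && e < err) {
          values <- cand; err <- e; improved <- TRUE
          break
        }
      }
    }
    if (n_eval + 2 > budget) break
    if (!improved) {
      step <- 1 + (step - 1) * shrink
      if (step - 1 < 1e-3) break
    }
  }
  structure(values, error = err, initial_error = err0, n_eval = n_eval)
}

#' Full reduced-model estimation for a challenge package
#'
#' Chains the three direct estimators over the unknown set (calibrating on
#' the disclosed non-unknown wild-type values), assembles a complete
#' submission, and optionally refines it by phenotype matching.
#'
#' @param pkg a `challenge_package`.
#' @param refine run [refine_by_matching()] after the direct estimates.
#' @param budget refinement evaluation budget.
#' @param mode simulation mode for the refinement evaluations.
#' @return list with `values` (named submission vector over the unknowns),
#'   `table` (the combined `reduced_estimate`), and `refined` attributes when
#'   refinement ran.
#' @export
fit_reduced <- function(pkg, refine = FALSE, budget = 300,
                        mode = "deterministic") {
  spec <- pkg$spec
  wt <- param_values(pkg$wildtype)
  unk <- pkg$unknowns
  bundle <- pkg$mutant_bundle

  u_bp <- unk$name[unk$class == "binding_probability"]
  u_th <- unk$name[unk$class == "rna_half_life"]
  u_kc <- unk$name[unk$class == "turnover_number"]

  known_bp <- wt[setdiff(names(wt)[pkg$wildtype$class == "binding_probability"],
                         unk$name)]
  tabs <- list()
  p_full <- known_bp
  if (length(u_bp)) {
    tabs$bp <- estimate_bind_probs(bundle, spec, u_bp, known_bp,
                                   analytic_fallback = TRUE)
    p_full <- c(p_full, stats::setNames(tabs$bp$estimate, tabs$bp$name))
  }
  if (length(u_th))
    tabs$th <- estimate_half_lives(bundle, spec, u_th, p_full)
  if (length(u_kc))
    tabs$kc <- estimate_kcats(bundle, spec, u_kc)
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  values <- stats::setNames(tab$estimate, tab$name)[unk$name]

  out <- list(values = values, table = tab)
  if (refine) {
    ev <- make_challenge_eval(pkg, mode = mode)
    fold_eval <- function(v) eval_candidate(ev, v / wt[names(v)])$error
    ref <- refine_by_matching(values, fold_eval, budget = budget)
    out$values <- stats::setNames(as.numeric(ref), names(ref))
    out$refined <- TRUE
    out$refine_error <- attr(ref, "error")
    out$refine_initial_error <- attr(ref, "initial_error")
  }
  out
}
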