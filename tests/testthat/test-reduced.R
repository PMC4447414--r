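test_that("noise-free bundles identify all three parameter classes within 1%", {
  pkg <- tc_det_pkg()
  truth <- param_values(challenge_truth(pkg)$mutant)[pkg$unknowns$name]
  fr <- fit_reduced(pkg)
  expect_setequal(names(fr$values), pkg$unknowns$name)
  expect_within_rel(fr$values[names(truth)], truth, 0.01)
  # each estimator touches only its own class
  expect_true(all(fr$table$class[fr$table$method == "chip_copy"] ==
                    "binding_probability"))
  expect_true(all(fr$table$class[fr$table$method == "halflife_ss"] ==
                    "rna_half_life"))
  expect_true(all(fr$table$class[fr$table$method == "kcat_flux"] ==
                    "turnover_number"))
})

test_that("a stochastic 32-cell bundle identifies unknowns to ~15% median", {
  pkg <- tc_pkg()
  truth <- param_values(challenge_truth(pkg)$mutant)[pkg$unknowns$name]
  fr <- fit_reduced(pkg)
  rel <- abs(fr$values[names(truth)] / truth - 1)
  expect_lte(median(rel), 0.15)
})

test_that("binding-probability estimates scale inversely with copy number", {
  pkg <- tc_det_pkg()
  spec <- pkg$spec
  known <- param_values(pkg$wildtype)
  known_bp <- known[setdiff(names(known)[pkg$wildtype$class ==
                                           "binding_probability"],
                            pkg$unknowns$name)]
  targets <- pkg$unknowns$name[pkg$unknowns$class == "binding_probability"][1:2]
  e1 <- estimate_bind_probs(pkg$mutant_bundle, spec, targets, known_bp,
                            analytic_fallback = TRUE)
  # under the fixed analytic calibration, doubling the DNA-seq profile at
  # fixed ChIP counts halves the estimate (with calibration genes the fitted
  # alpha absorbs a global copy rescaling, so the fixed-alpha path is probed)
  b2 <- pkg$mutant_bundle
  i <- b2$registry$data_class == "dnaseq"
  b2$mean[i] <- 2 * b2$mean[i]
  e1a <- estimate_bind_probs(pkg$mutant_bundle, spec, targets,
                             calibration = NULL, analytic_fallback = TRUE)
  e2 <- estimate_bind_probs(b2, spec, targets, calibration = NULL,
                            analytic_fallback = TRUE)
  expect_equal(e2$estimate, e1a$estimate / 2, tolerance = 1e-9)
  # zero counts flag the gene and land on the positive floor
  b3 <- pkg$mutant_bundle
  j <- which(b3$registry$data_class == "chipseq" &
               b3$registry$entity == sub("^p_", "", targets[1]))
  b3$mean[j] <- 0
  e3 <- estimate_bind_probs(b3, spec, targets, known_bp,
                            analytic_fallback = TRUE)
  expect_match(e3$flag[1], "inestimable")
  expect_gt(e3$estimate[1], 0)
  expect_error(estimate_bind_probs(pkg$mutant_bundle, spec, targets,
                                   calibration = NULL),
               "calibration error")
})

test_that("half-life estimates scale linearly with expression", {
  pkg <- tc_det_pkg()
  targets <- pkg$unknowns$name[pkg$unknowns$class == "rna_half_life"][1:2]
  genes <- sub("^thalf_", "", targets)
  p <- param_values(challenge_truth(pkg)$mutant)[paste0("p_", genes)]
  e1 <- estimate_half_lives(pkg$mutant_bundle, pkg$spec, targets, p)
  b2 <- pkg$mutant_bundle
  i <- which(b2$registry$data_class == "rna_array" &
               b2$registry$entity %in% genes)
  b2$mean[i] <- 2 * b2$mean[i]
  e2 <- estimate_half_lives(b2, pkg$spec, targets, p)
  # doubling expression at fixed synthesis roughly doubles the half-life
  # (the replication-transient correction makes it slightly super-linear)
  expect_true(all(e2$estimate / e1$estimate > 1.8))
  # zero synthesis is flagged inestimable
  e3 <- estimate_half_lives(pkg$mutant_bundle, pkg$spec, targets,
                            stats::setNames(rep(0, 2), paste0("p_", genes)))
  expect_true(all(grepl("inestimable", e3$flag)))
})

test_that("turnover estimates invert the saturable flux law", {
  pkg <- tc_det_pkg()
  targets <- pkg$unknowns$name[pkg$unknowns$class == "turnover_number"][1:3]
  e1 <- estimate_kcats(pkg$mutant_bundle, pkg$spec, targets)
  # halving the enzyme abundance at fixed flux doubles the estimate
  b2 <- pkg$mutant_bundle
  rxn <- sub("^kcat_", "", targets)
  ri <- match(rxn, pkg$spec$reaction_names)
  enz <- pkg$spec$gene_names[pkg$spec$metabolic_genes[ri]]
  i <- which(b2$registry$data_class == "protein_array" &
               b2$registry$entity %in% enz)
  b2$mean[i] <- b2$mean[i] / 2
  e2 <- estimate_kcats(b2, pkg$spec, targets)
  expect_equal(e2$estimate, 2 * e1$estimate, tolerance = 1e-9)
  # deep saturation: the estimate approaches flux / enzyme
  b3 <- pkg$mutant_bundle
  j <- b3$registry$data_class == "metabolite_concentrations"
  b3$mean[j] <- 1e9
  e3 <- estimate_kcats(b3, pkg$spec, targets)
  fx <- bundle_slice(pkg$mutant_bundle, "reaction_fluxes")
  pr <- bundle_slice(pkg$mutant_bundle, "protein_array")
  ve <- fx$mean[match(rxn, fx$entity)] / pr$mean[match(enz, pr$entity)]
  expect_equal(e3$estimate, ve, tolerance = 1e-6)
})

test_that("refinement is greedy, monotone and recovers a planted error", {
  target <- c(a = 1, b = 2, c = 0.5)
  eval_fn <- function(v) sum((log(v) - log(target))^2)
  # starting at the optimum, nothing moves
  r0 <- refine_by_matching(target, eval_fn, budget = 50)
  expect_equal(as.numeric(r0), unname(target))
  expect_equal(attr(r0, "error"), attr(r0, "initial_error"))
  # a single 2x perturbation is pulled back
  start <- target
  start["b"] <- target["b"] * 2
  r1 <- refine_by_matching(start, eval_fn, budget = 400)
  expect_lt(abs(r1[["b"]] / target[["b"]] - 1), 0.1)
  expect_lte(attr(r1, "error"), attr(r1, "initial_error"))
  # monotone even on a rugged surface
  set.seed(6)
  rug <- function(v) sum((log(v))^2) + 0.1 * sum(sin(20 * v))
  r2 <- refine_by_matching(c(a = 1.5, b = 0.7), rug, budget = 120)
  expect_lte(attr(r2, "error"), attr(r2, "initial_error"))
})

test_that("estimates sharpen as the population grows", {
  pkg <- tc_pkg()
  spec <- pkg$spec
  truth <- challenge_truth(pkg)$mutant
  tv <- param_values(truth)[pkg$unknowns$name]
  med_err <- function(n_cells, seed) {
    p2 <- pkg
    p2$mutant_bundle <- simulate_population(spec, truth, n_cells, seed = seed)
    fr <- fit_reduced(p2)
    median(abs(fr$values[names(tv)] / tv - 1))
  }
  seeds <- 1:5
  small <- vapply(seeds, function(s) med_err(8, s), 0.0)
  large <- vapply(seeds, function(s) med_err(64, s + 100), 0.0)
  expect_lt(median(large), median(small))
})
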