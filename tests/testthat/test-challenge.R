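spec <- tc_spec()
wt <- spec$wildtype

test_that("structurally disconnected parameters have zero growth sensitivity", {
  # gene g10 is non-metabolic: its half-life has no causal path to growth
  s_det <- estimate_sensitivity(spec, wt, "thalf_g10", mode = "deterministic")
  expect_equal(s_det, 0)
  s_sto <- estimate_sensitivity(spec, wt, "thalf_g10", n_cells = 8, seed = 3)
  expect_lt(abs(s_sto), 0.05)
  # more enzyme never slows growth in this surrogate
  for (nm in c("p_g01", "p_g05", "kcat_r04"))
    expect_lte(estimate_sensitivity(spec, wt, nm, mode = "deterministic"), 0)
})

test_that("finite-difference sensitivities agree with a dense stencil oracle", {
  lnT <- function(nm, s) {
    p <- wt
    p$value[p$name == nm] <- p$value[p$name == nm] * exp(s)
    log(doubling_time(simulate_cell(spec, p, mode = "deterministic")))
  }
  for (nm in c("kcat_r02", "p_g03")) {
    got <- estimate_sensitivity(spec, wt, nm, rel_step = 0.5,
                                mode = "deterministic")
    # 9-point central stencil on the log-log response
    h <- log(1.5) / 4
    w <- c(3, -32, 168, -672, 0, 672, -168, 32, -3) / 840
    oracle <- sum(w * vapply(-4:4, function(k) lnT(nm, k * h), 0.0)) / h
    expect_within_rel(got, oracle, 0.05)
  }
})

test_that("step planning follows the log-linear rule with floor and clip", {
  # sensitivity exactly -1: fold change exp(-ln 1.019)
  f <- plan_step(c(a = -1), 0.019)
  expect_equal(unname(f["a"]), exp(-log(1.019)), tolerance = 1e-12)
  expect_equal(unname(f["a"]), 0.98135, tolerance = 1e-4)
  # unit positive sensitivity
  expect_equal(unname(plan_step(c(a = 1), 0.019)["a"]), 1.019)
  # floored names are excluded; all-floored errors
  f2 <- plan_step(c(a = -1, b = 1e-6), 0.019)
  expect_named(f2, "a")
  expect_error(plan_step(c(b = 1e-6), 0.019), "no candidate")
  # clipping bounds the planned change
  f3 <- plan_step(c(a = -0.002), 0.019, max_log_fold = 2.5)
  expect_equal(unname(f3["a"]), exp(-2.5))
})

test_that("mutant construction modifies the configured number of parameters", {
  st <- build_mutant(spec, seed = 7)
  expect_equal(nrow(st$modifications), 15)
  expect_false(anyDuplicated(st$modifications$name) > 0)
  # unmodified names keep their wild-type values
  un <- setdiff(wt$name, st$modifications$name)
  expect_equal(param_values(st$mutant)[un], param_values(wt)[un])
  # the 33% slow-growth target, within simulation noise
  expect_gte(st$achieved_ratio, 1.25)
  expect_lte(st$achieved_ratio, 1.41)
})

test_that("a zero-step construction returns the wild type untouched", {
  st <- build_mutant(spec, n_steps = 0, seed = 1)
  expect_equal(st$mutant, wt)
  expect_equal(nrow(st$modifications), 0)
  expect_equal(st$achieved_ratio, 1)
})

test_that("deterministic construction has a non-decreasing doubling-time ratio", {
  st <- build_mutant(spec, n_steps = 6, seed = 3, mode = "deterministic")
  ratios <- vapply(st$step_log, function(s) s$achieved_ratio, 0.0)
  expect_true(all(diff(ratios) >= -1e-9))
})

test_that("unknown selection matches size and class proportions", {
  st <- build_mutant(spec, seed = 7)
  u <- select_unknowns(st, seed = 7)
  expect_equal(nrow(u), 30)
  expect_true(all(st$modifications$name %in% u$name))
  expect_equal(nrow(select_unknowns(st, n_extra = 0, seed = 1)), 15)

  # proportional-rounding oracle on an ample-pool layout (18 reactions)
  spec18 <- cell_model_spec(n_genes = 24, metabolic_genes = 1:18)
  mods <- c(paste0("p_g0", 1:3), paste0("thalf_g0", 4:6),
            sprintf("kcat_r%02d", 1:9))
  fake <- structure(list(
    wildtype = spec18$wildtype,
    modifications = data.frame(name = mods)), class = "mutant_strain")
  u2 <- select_unknowns(fake, n_extra = 15, seed = 5)
  extras <- setdiff(u2$name, mods)
  got <- table(spec18$wildtype$class[match(extras, spec18$wildtype$name)])
  expect_equal(as.integer(got[c("binding_probability", "rna_half_life",
                                "turnover_number")]), c(3L, 3L, 9L))
  expect_false(attr(u2, "redistributed"))
})

test_that("the default challenge package has the published structure", {
  pkg <- tc_pkg()
  expect_equal(nrow(pkg$unknowns), 30)
  expect_equal(nrow(challenge_truth(pkg)$modifications), 15)
  expect_equal(mutant_dataset_count(pkg), 8)
  expect_equal(perturbation_dataset_count(pkg), 480)
  expect_equal(remaining_budget(pkg), 50)
  expect_equal(pkg$mutant_bundle$n_cells, 32)
  expect_true(all(vapply(pkg$perturbations, function(b) b$n_cells, 0) == 8))
})

test_that("package generation is reproducible from (spec, seed)", {
  p1 <- generate_challenge(spec, seed = 9, n_cells_mutant = 4,
                           n_cells_perturb = 2)
  p2 <- generate_challenge(spec, seed = 9, n_cells_mutant = 4,
                           n_cells_perturb = 2)
  expect_identical(p1$mutant_bundle$mean, p2$mutant_bundle$mean)
  expect_identical(p1$unknowns, p2$unknowns)
  expect_identical(lapply(p1$perturbations, `[[`, "mean"),
                   lapply(p2$perturbations, `[[`, "mean"))
  expect_identical(param_values(challenge_truth(p1)$mutant),
                   param_values(challenge_truth(p2)$mutant))
})

test_that("the perturbation budget counts distinct releases and then errors", {
  pkg <- generate_challenge(spec, seed = 5, n_cells_mutant = 4,
                            n_cells_perturb = 2, budget = 3)
  n1 <- request_perturbation(pkg, pkg$unknowns$name[1], "up", "rnaseq")
  expect_s3_class(n1, "data.frame")
  expect_equal(remaining_budget(pkg), 2)
  # duplicate request is free
  request_perturbation(pkg, pkg$unknowns$name[1], "up", "rnaseq")
  expect_equal(remaining_budget(pkg), 2)
  request_perturbation(pkg, pkg$unknowns$name[1], "down", "rnaseq")
  request_perturbation(pkg, pkg$unknowns$name[2], "up", "chipseq")
  expect_equal(remaining_budget(pkg), 0)
  expect_error(request_perturbation(pkg, pkg$unknowns$name[3], "up", "rnaseq"),
               "budget")
  # conditions outside the unknown set are rejected
  expect_error(request_perturbation(pkg, "not_a_parameter", "up", "rnaseq"),
               "lookup")
})

test_that("challenge packages round-trip through the directory layout", {
  pkg <- generate_challenge(spec, seed = 13, n_cells_mutant = 4,
                            n_cells_perturb = 2)
  d <- withr::local_tempdir()
  write_challenge(pkg, d)
  expect_true(file.exists(file.path(d, "truth.tsv.sealed")))
  pkg2 <- read_challenge(d)
  expect_equal(pkg2$unknowns$name, pkg$unknowns$name)
  expect_equal(pkg2$mutant_bundle$mean, pkg$mutant_bundle$mean)
  expect_equal(remaining_budget(pkg2), remaining_budget(pkg))
  expect_equal(param_values(challenge_truth(pkg2)$mutant),
               param_values(challenge_truth(pkg)$mutant))
  expect_equal(length(pkg2$perturbations), length(pkg$perturbations))
})
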