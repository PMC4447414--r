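cfg <- derf_config(budget = 600, seed = 3)

test_that("initial populations respect size, bounds and determinism", {
  pop <- init_population(cfg, 4)
  expect_length(pop, 200)
  xs <- t(sapply(pop, `[[`, "x"))
  expect_true(all(xs >= cfg$bounds[1] & xs <= cfg$bounds[2]))
  expect_true(all(vapply(pop, function(i) i$tag, "") == "init"))
  expect_true(all(is.na(vapply(pop, function(i) i$error, 0.0))))
  expect_identical(init_population(cfg, 4), init_population(cfg, 4))
  expect_error(derf_config(pop_size = 3), "pop_size")
})

test_that("the DE mutation rule is x_p + F (x_q - x_r) with ordered pair", {
  mk <- function(x, e) { i <- new_individual(x, "init"); i$error <- e; i }
  # degenerate triple: proposal equals x_p for any F
  pop3 <- list(mk(c(1, 1), 1), mk(c(1, 1), 2), mk(c(1, 1), 3))
  expect_equal(de_propose(pop3, cfg)$x, c(1, 1))
  # hand-computed proposal with fixed F; q/r ordered so q has lower error
  found_q_first <- FALSE; found_q_second <- FALSE
  for (s in 1:20) {
    set.seed(s)
    pop <- list(mk(c(1, 1), 5), mk(c(1.5, 1), 1), mk(c(0.5, 1), 9))
    cand <- de_propose(pop, cfg, F = 0.5)
    # whichever roles p,q,r land in, q must be the lower-error of the pair
    expect_true(all(cand$x >= cfg$bounds[1] & cand$x <= cfg$bounds[2]))
    if (isTRUE(all.equal(cand$x, c(1.5, 1)))) found_q_first <- TRUE
  }
  expect_true(found_q_first)  # x_p=(1,1), q=(1.5,1), r=(0.5,1): 1 + 0.5*1 = 1.5
  # out-of-range coordinates are clamped to the bounds exactly
  popb <- list(mk(c(1.9, 1), 1), mk(c(1.9, 1), 2), mk(c(0.1, 1), 3))
  set.seed(1)
  cb <- de_propose(popb, cfg, F = 1)
  expect_true(all(cb$x <= 1.906 & cb$x >= 0.066))
  expect_error(de_propose(popb[1:2], cfg), "3 evaluated")
})

test_that("acceptance requires error strictly below the population median", {
  mk <- function(x, e) { i <- new_individual(x, "init"); i$error <- e; i }
  pop <- list(mk(1, 1), mk(2, 2), mk(3, 3))  # median error 2
  eval_fixed <- function(v) v[1]              # error equals the coordinate
  above <- accept_candidate(pop, new_individual(5, "de"), eval_fixed, cfg)
  expect_false(above$accepted)
  expect_length(above$pop, 3)
  at_median <- accept_candidate(pop, new_individual(2, "de"), eval_fixed, cfg)
  expect_false(at_median$accepted)  # strict inequality
  below <- accept_candidate(pop, new_individual(0.5, "de"), eval_fixed, cfg)
  expect_true(below$accepted)
  expect_length(below$pop, 4)
  # cap eviction removes the worst member
  small <- derf_config(pop_size = 4, pop_cap = 4, seed = 1)
  pop4 <- list(mk(1, 1), mk(2, 2), mk(3, 3), mk(9, 9))
  res <- accept_candidate(pop4, new_individual(0.5, "de"), eval_fixed, small)
  expect_length(res$pop, 4)
  expect_false(any(vapply(res$pop, function(i) i$error, 0.0) == 9))
  # evaluation failure discards the candidate with a cause
  bad <- accept_candidate(pop, new_individual(1, "de"),
                          function(v) stop("boom"), cfg)
  expect_false(bad$accepted)
  expect_match(bad$cause, "boom")
})

test_that("the feature basis captures variance targets and reconstructs", {
  set.seed(7)
  # rank-1 data: one component explains everything
  u <- rnorm(50); v <- rnorm(6)
  r1 <- outer(u, v) + matrix(rnorm(300, 0, 1e-9), 50)
  b1 <- fit_feature_basis(r1, derf_config(pca_target = 0.4, pca_min = 1))
  expect_equal(b1$k, 1)
  expect_gt(b1$explained[1], 0.999)
  # isotropic noise: retained count equals the eigenvalue-spectrum oracle
  iso <- matrix(rnorm(500 * 50), 500, 50)
  bi <- fit_feature_basis(iso, derf_config(pca_target = 0.40, pca_min = 1))
  ev <- eigen(stats::cor(iso), symmetric = TRUE, only.values = TRUE)$values
  k_oracle <- min(which(cumsum(ev) / sum(ev) >= 0.40))
  expect_equal(bi$k, k_oracle)
  expect_gt(bi$k, 5)          # several components, not a collapse to one
  expect_lt(bi$k, 0.40 * 50 + 3)
  # the default configuration keeps at least its component floor
  bf <- fit_feature_basis(iso, derf_config())
  expect_gte(bf$k, 24)
  # orthonormal axes; projection of a retained-subspace vector is lossless
  g <- t(bi$rotation) %*% bi$rotation
  expect_equal(g, diag(bi$k), tolerance = 1e-8, ignore_attr = TRUE)
  z <- rnorm(bi$k)
  x <- as.numeric(bi$rotation %*% z) * bi$scale + bi$center
  expect_equal(as.numeric(project_features(bi, matrix(x, 1))), z,
               tolerance = 1e-8)
  expect_error(fit_feature_basis(matrix(1, 5, 3)), "degenerate")
})

test_that("random forests learn signal and not permuted noise", {
  set.seed(8)
  n <- 500
  f <- matrix(rnorm(n * 5), n, 5)
  y <- 2 * f[, 1] - f[, 3]
  st <- train_rf(f, cbind(a = y), derf_config())
  expect_gte(st$oob_r2[["a"]], 0.8)
  st_perm <- train_rf(f, cbind(a = sample(y)), derf_config())
  expect_lte(st_perm$oob_r2[["a"]], 0.1)
  # constant targets are predicted as that constant
  st_c <- train_rf(f[1:50, ], cbind(a = rep(2, 50)), derf_config())
  pr <- stats::predict(st_c$forests[["a"]],
                       data = stats::setNames(as.data.frame(f[1:3, ]),
                                              paste0("pc", 1:5)))$predictions
  expect_equal(pr, rep(2, 3))
  expect_error(train_rf(f[1:5, ], cbind(a = y[1:5])), ">= 10")
})

test_that("rf proposals fall back to the best phenotype and respect bounds", {
  set.seed(9)
  n <- 80
  xs <- matrix(runif(n, 0.5, 1.5), n, 1, dimnames = list(NULL, "a"))
  phen <- cbind(xs[, 1] + rnorm(n, 0, 0.01), rnorm(n))
  basis <- fit_feature_basis(phen, derf_config(pca_target = 0.9))
  st <- train_rf(project_features(basis, phen), xs, derf_config())
  mk <- function(x, e, ph) {
    i <- new_individual(c(a = x), "de"); i$error <- e; i$phenotype <- ph; i
  }
  pop <- list(mk(1.0, 0.1, phen[1, ]), mk(1.4, 5, phen[2, ]))
  prop <- rf_propose(st, pop, basis, derf_config())
  expect_equal(prop$tag, "rf")
  expect_true(prop$x >= 0.066 && prop$x <= 1.906)
  # fixed point: forests trained on a constant coordinate reproduce it
  stc <- train_rf(project_features(basis, phen),
                  matrix(1.2, n, 1, dimnames = list(NULL, "a")),
                  derf_config())
  propc <- rf_propose(stc, pop, basis, derf_config())
  expect_equal(unname(propc$x), 1.2, tolerance = 1e-9)
  expect_error(rf_propose(list(), pop, basis), "rf_ensemble")
})

test_that("pure DE minimizes a sphere and keeps its invariants", {
  target <- c(0.5, 1.2, 0.8, 1.5, 0.3)
  sphere <- function(x) sum((x - target)^2)
  res <- run_derf(sphere, derf_config(budget = 2000, seed = 5,
                                      rf_period = 10000), n_dim = 5)
  expect_lt(res$best$error, 0.15)
  # scalar-error objective: no phenotypes, hence no rf provenance
  expect_false("rf" %in% res$trace$provenance)
  # best-ever error is non-increasing
  expect_true(all(diff(res$trace$best_so_far) <= 1e-12))
  # bound invariance across every evaluated candidate
  expect_true(all(res$archive$x >= 0.066 & res$archive$x <= 1.906))
  # median-threshold acceptance is replayable from the trace
  post <- res$trace[res$trace$eval > 200, ]
  expect_true(all(post$accepted == (post$error < post$median_before)))
  expect_error(run_derf(sphere, derf_config(budget = 100), n_dim = 5),
               "budget")
})

test_that("runs are reproducible under a fixed seed", {
  sphere <- function(x) sum((x - 1)^2)
  r1 <- run_derf(sphere, derf_config(budget = 400, seed = 11), n_dim = 3)
  r2 <- run_derf(sphere, derf_config(budget = 400, seed = 11), n_dim = 3)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best$x, r2$best$x)
})
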