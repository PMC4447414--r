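# shared fixtures, built in code at test time

# default surrogate; cheap enough to build per file
tc_spec <- function(...) cell_model_spec(...)

# a small challenge package reused across files (built once per test run)
tc_pkg <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$pkg)) cache$pkg <- generate_challenge(tc_spec(), seed = 42)
    cache$pkg
  }
})

# deterministic-mode bundle of the sealed mutant (noise-free data)
tc_det_pkg <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$pkg)) {
      pkg <- tc_pkg()
      pkg$mutant_bundle <- simulate_population(
        pkg$spec, challenge_truth(pkg)$mutant, n_cells = 4, seed = 1,
        mode = "deterministic")
      cache$pkg <- pkg
    }
    cache$pkg
  }
})

expect_within_rel <- function(actual, expected, tol) {
  expect_true(all(abs(actual / expected - 1) <= tol),
              label = sprintf("max relative deviation %.4g <= %.4g",
                              max(abs(actual / expected - 1)), tol))
}
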