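---
title: "A desk-scale whole-cell parameter-estimation benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale whole-cell parameter-estimation benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Why a surrogate cell

Estimating the parameters of genome-scale whole-cell models is brutally
expensive: a single simulated life cycle of such a model costs on the order
of a CPU-day, which rules out the thousands of evaluations that population
optimizers need. `toycell` replaces the full model with a stochastic
surrogate cell that runs in about a millisecond while keeping the feature
that makes the estimation problem interesting: a doubling-time phenotype
that depends on three structurally identifiable parameter classes, each
mapped onto its own data channel.

* **Promoter binding probabilities** `p_g` drive transcription initiation,
  and are read out (with copy-number confounding) by the ChIP-seq channel.
* **RNA half-lives** `t½_g` set the decay rates; together with the ChIP-seq
  synthesis information, RNA abundances pin them down.
* **Turnover numbers** `kcat_r` set metabolic flux capacity; fluxes plus
  enzyme abundances expose them.

This identifiability layout is the point of the design: every unknown can in
principle be recovered from the released data, yet only through the right
combination of channels.

## The surrogate dynamics

One cell is advanced on a fixed grid `dt` (default 0.01, about 1% of the
wild-type doubling time; time is in units of roughly one wild-type cycle).
Per step:

1. **Copy number.** Replication initiates when mass crosses
   `repl_mass = 1.25` (in units of birth mass); two forks move symmetrically
   from the origin (position 0) to the terminus (position 0.5) at
   `fork_speed = 1` chromosome fraction per unit time. A gene at distance
   `d` from the origin has copy number 2 once a fork passes it. During the
   step in which a fork passes, the synthesis rate uses the fractional
   coverage of the step, which keeps the deterministic trajectory smooth in
   the parameters.
2. **Transcription.** Events per gene are Poisson with mean
   `c_g p_g k_txn dt` (`k_txn = 1000` events per unit time per copy at
   `p = 1`). Lifetime initiation counts are accumulated as the ChIP-seq
   analogue. Deterministic mode propagates means, using the exact
   exponential birth–death update over the step so grid points match the
   underlying ODE.
3. **Decay.** Per-molecule survival `exp(-ln 2 dt / t½_g)`; binomial in
   stochastic mode.
4. **Translation.** Poisson protein synthesis with mean `k_tl RNA_g dt`
   (`k_tl = 10`), no active protein decay — dilution happens implicitly at
   division. Initial protein is `k_tl RNA_0 tau_p` with `tau_p = 1.3`, so a
   cell roughly doubles its enzyme content over a cycle.
5. **Metabolism.** Each reaction `r` carries flux
   `v_r = kcat_r E_r S/(K + S)` with `K = 1`. The metabolite pools relax
   (rate `k_relax = 30`) toward a homeostatic set point `S* = 2` scaled by
   `(specific flux / wild-type specific flux)^0.3`. The small exponent keeps
   the pools informative about kcat changes while staying nearly constant
   within a cycle — which is what makes the flux-law inversion used by the
   reduced estimators accurate.
6. **Growth.** `mu = mu0 * geometric mean over r of clamp(v_r / v_ref_r,
   0.02, 3)`, with `v_ref_r` the wild-type birth-state flux and
   `mu0 = 0.48`. The geometric mean makes every reaction rate-limiting in
   part, so every kcat (and, through enzyme abundance, every metabolic
   gene's `p` and `t½`) moves the doubling time. Mass multiplies by
   `(1 + mu dt)` per step; volume tracks mass.
7. **Division.** Cytokinesis at `max(t_completion, t_mass-doubling)`, both
   interpolated inside the step, so the doubling time is a smooth function
   of the parameters rather than quantized to the grid. A cell that fails
   to divide before `max_time = 4` carries an explicit timeout flag.

The default layout is 12 genes (9 of them enzymes, one per reaction), 9
reactions and 3 metabolite pools: small enough for millisecond simulation,
large enough to host 30 unknowns across the three classes.

### What the generator does and does not emulate

Cell-to-cell variation is purely intrinsic (Poisson/binomial event noise and
Poisson initial counts); there is no measurement noise on the single-cell
channels, matching the challenge setting where only model stochasticity
separated replicate cells. The RNA-seq and RNA-array channels share one
latent signal and differ only in their noise dialect (count sampling at
depth 20 versus multiplicative log-normal with sd 0.1) — distinct data sets,
one underlying quantity. Not emulated: sequence-level biology, multi-gene
operons, FBA-style metabolism, multi-generation lineages, or extrinsic
noise. Passing tests therefore demonstrate method behaviour under the
surrogate's statistical structure, not performance on a real whole-cell
model.

## Challenge construction

The mutant strain is built exactly as a slow-growth strain would be: for
each step, the elasticity `d ln T / d ln v` of the doubling time to every
not-yet-modified parameter is measured by central log-differences (common
random seeds across the two endpoints in stochastic mode); the fold change
that would raise the doubling time by 1.9% is planned per parameter
(`log-fold = ln(1.019) / sensitivity`, clipped at |2.5|, parameters with
|sensitivity| < 1e-3 excluded); one parameter is drawn with probability
proportional to its planned |log fold| and modified. Fifteen steps compound
to `1.019^15 ≈ 1.33`, the 33% doubling-time increase — the multiplicative
reading is the one consistent with the stated per-step and total targets.
Whether the historical weighting favoured large or small planned changes is
not stated anywhere we could find; both readings are implemented
(`weighting = "fold"` or `"inverse_fold"`), with proportional-to-|log-fold|
as the default.

Step sensitivities default to deterministic mode: they are exact, cheap and
give stable selection weights; the achieved doubling time is still logged
from stochastic populations so the construction log reflects the simulator
the data come from.

The unknown set is the 15 modified names plus 15 unmodified decoys matched
to the modified class proportions by largest-remainder rounding. With only
9 reactions a kcat-heavy mutant can exhaust the unmodified kcat pool; the
shortfall is then redistributed to classes with room (flagged
`redistributed`) rather than failing — an accommodation to the toy model's
size, not present in larger layouts.

The perturbation library holds 2-fold up/down versions of the sealed mutant
for all 30 unknowns, 8 cells per condition, and releases one
(condition, data-class) pair per request against a budget of 50 distinct
requests; repeats are free. 60 conditions by 8 data classes gives the 480
perturbation data sets of a full package.

## Scoring

The parameter error is the mean squared log10 ratio over the 30 unknowns;
the prediction error the mean squared z-score over measurements, using the
mutant bundle's cross-cell variances. Two conventions are ours: variances at
or below `1e-12` are excluded (and counted) rather than divided by, and
empirical p-values use add-one smoothing `(1 + #{meta <= obs}) / (n_meta +
1)` so the combined score `s = -ln(p_param p_predict)` is always finite.
Meta vectors resample each coordinate independently from the pool, the
literal reading of coordinate-wise resampling; joint row resampling is
available as an option. The per-parameter analytics use Spearman rank
correlation — robust to the heavy-tailed error scale. The open question of
how the cross-cell variance entered the historical scoring (sample variance
versus known model variance) is resolved here as: the bundle stores the
unbiased sample variance across its cells, and flags that choice in its
manifest.

## The DE–RF estimator

Individuals are fold-change vectors over the unknowns, bounded to
[0.066, 1.906]. The population is initialized to 200 individuals drawn
log-uniformly over the bounds; mutation is `x_p + F (x_q - x_r)` with the
lower-error member of the pair as `x_q`, `F ~ U(0.2, 1)`, no crossover;
a candidate enters only if its error is strictly below the current
population median. Unbounded population growth is unworkable, so a cap
(default 400; 200 works better at small budgets) evicts the worst member.

Every `rf_period` evaluations the archive of evaluated candidates (including
rejected ones — they carry information and are kept by default) is reduced
by principal components and one regression forest per unknown is trained to
map reduced phenotype to that parameter's fold change. Two choices matter
here and were made after the obvious alternatives failed:

* **Correlation-scale PCA with a component floor.** The measurement classes
  live on wildly different scales, so unscaled axes are dominated by the
  largest counts; and with only ~90 measurements the 40% explained-variance
  target alone retains 2–3 components, far too few to resolve 30
  parameters. The basis therefore scales columns to unit variance and keeps
  at least `pca_min = 24` axes (several dozen, as the feature reduction is
  meant to deliver) up to a cap of 50.
* **Inversion at the observed phenotype.** Forest predictions are evaluated
  at the *mutant bundle's* measurement vector, so each epoch proposes a
  direct inverse estimate of the truth. Predicting at the best individual's
  own phenotype instead is nearly circular — the forests simply reproduce
  the best individual — and is kept only as the fallback when no target
  vector is supplied.

Forest cost is the practical bottleneck of a run, so three efficiency knobs
are exposed: a per-epoch training-row cap (`rf_train_cap`, keeping the
lowest-error evaluations, which also focuses the inverse map near the
optimum), per-tree row subsampling without replacement
(`sample_fraction = 0.632`), and the tree count. Retraining only a rotating
subset of the per-parameter forests was tried and discarded: proposals that
replace all coordinates at once are what drive convergence.

All randomness flows from the config seed; the trace records every
evaluation's error, provenance, pre-acceptance median and acceptance flag,
so bound and median-threshold invariants are replayable after the fact.

## Reduced physical-model estimators

Three closed-form inversions of the surrogate's steady states:

* `p̂_g ∝ chip_g / copy_g`, with copy numbers interpolated from the DNA-seq
  gradient at the gene's position and the proportionality constant fit on
  genes whose binding probabilities are not in the unknown set (falling
  back to the disclosed `1/(k_txn T)` when no such gene remains).
* `t̂½_g` solves the time-averaged birth–death balance
  `RNA̅ = (p k_txn / λ)(c̅ - (1 - e^{-λΔ})/(λT))`, where `Δ = (c̅-1)T` is the
  post-duplication interval implied by the gene's mean copy number. The
  transient term matters: ignoring it biases half-lives by several percent
  in noise-free data, while the corrected inversion recovers them to
  well under 1%.
* `k̂cat_r = v̅_r / (E̅_r S̅/(K + S̅))`, the flux law inverted with
  time-averaged means; the saturation term uses the time-averaged metabolite
  concentration (first-order approximation — its error is measured, not
  assumed, by the noise-free recovery tests).

Optional refinement runs a cyclic coordinate search (multiplicative steps,
initial factor 1.1, halving the step after a full stale cycle) that accepts
only error-decreasing moves — a stand-in for short-timescale re-simulation
refinement, labelled as such.

## Numerical choices and test problem sizes

Event times are interpolated within steps; time averages are trapezoidal
over the actual (uneven) grid including the final partial step; the
deterministic RNA update is the exact exponential solution over each step.
Degenerate inputs follow explicit contracts: populations need at least two
cells, undivided cells are excluded from event statistics and counted,
candidates that fail to divide receive a large graded penalty
(`1e7 * mass deficit`) rather than an error, and zero counts or enzymes
flag a parameter inestimable at a positive floor instead of producing
non-positive estimates.

The test suite runs the full challenge generation once (32-cell mutant
bundle, 480 perturbation sets at 8 cells), the end-to-end direction-recovery
property at a 3,000-evaluation budget over 10 seeds, the pure-DE sphere
benchmark (d = 5, 5,000 evaluations, 10 seeds), and consistency runs at 8
versus 64 cells over 5 seeds — sizes chosen to exercise every property at
full fidelity while keeping a laptop run comfortable.

## Known limitations

The surrogate's identifiability is by construction cleaner than a real
whole-cell model's: its parameters are exactly identifiable from noise-free
data, so the benchmark measures estimator behaviour under stochasticity and
budget limits, not structural degeneracy. The empirical-null scoring is only
as meaningful as the submission pool it is fed. And the DE–RF method's
performance at a 3,000-evaluation budget depends on the RF inversion;
configurations that cripple it (tiny `pca_min`, no target phenotype) revert
to slow pure DE.
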