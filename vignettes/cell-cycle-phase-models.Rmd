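---
title: "Erlang phase models, coupling statistics, and the many-for-all simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Erlang phase models, coupling statistics, and the many-for-all simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erlangcycle)
```

## The scientific problem

Time-lapse microscopy of asynchronously dividing cells yields, for each
cell, five event times — birth, S-phase onset, S-phase end, nuclear
envelope breakdown, and telophase — and hence four phase durations (G1,
S, G2, M). Two empirical facts about these durations have to be
reconciled. First, each phase duration is well described by an Erlang
distribution (a gamma with integer shape): the phase behaves like a
sequence of `k` rate-limiting steps, each completing at rate `lambda`,
and the phases are statistically independent of one another — progression
is memoryless across phase boundaries. Second, phase durations are
strongly *heritable*: sister cells have highly correlated G1, S, and G2
durations. Naively these pull in opposite directions — if a cell carries
factors that set its pace, why doesn't a slow G1 predict a slow S?

The many-for-all model resolves the tension: a large number of heritable
factor types, each exerting a weak influence on the progression rate of
more than one phase, produces strong sister-sister correlations while the
net cross-phase coupling within a cell averages out to nothing. This
package implements that quantitative core end to end: the Erlang
maximum-likelihood machinery, the coupling statistics and their
measurement-noise bootstrap, the factor-model simulator, and synthetic
data generators (phase tables, sister lineages, reporter traces) that
stand in for microscopy data in every test.

## The Erlang model and its fitting

A phase duration `x` has density

$$f(x; k, \lambda) = \frac{\lambda^k x^{k-1} e^{-\lambda x}}{(k-1)!}\,\Delta T,$$

where the measurement interval `ΔT` converts a continuous density into a
per-frame observation probability. On the log scale `ΔT` is an additive
constant, so it can never change which `(k, λ)` maximizes the likelihood;
it is retained for fidelity and documented as argmax-neutral
(`erlang_log_pdf()`).

`fit_erlang_phase()` exploits the structure of the problem rather than a
generic optimizer: for fixed integer `k` the score equation
`dL/dλ = nk/λ − Σx = 0` gives the conditional maximizer `λ(k) = k/mean(x)`
in closed form, so the joint MLE reduces to an exhaustive, deterministic
scan of the profile log-likelihood over `k = 1..k_max` (default 500).
This is exact under the integer constraint, reproducible, and fast — a
fit at `n = 1000` costs a fraction of a millisecond; a generic simplex
search can neither guarantee the integer constraint nor the global
optimum. Ties on the log-likelihood resolve to the smallest `k`
(parsimony). Zero-variance data push the optimum to the `k_max` boundary,
which is reported with a warning rather than hidden. No refinement step
is needed after the scan: the profile rate *is* the exact conditional
maximizer.

The single-shared-rate ("simple Markovian") variant constrains all four
phases to one `λ` with free integer shapes. Given a shape vector the
conditional rate is again closed-form,
`λ = Σ_p n_p k_p / Σ_p Σ x_p`; `fit_shared_rate()` searches the shape
vector by coordinate ascent from seeded random restarts (plus one
moment-based start), verified in the tests against exhaustive enumeration
at small `k_max`. Because it is a nested submodel, its maximized
log-likelihood can never exceed the sum of the independent fits — the
package asserts this, and a likelihood-ratio comparison quantifies how
badly a single rate fits heterogeneous phases.

Uncertainty comes from a nonparametric bootstrap (`bootstrap_fit_sd()`,
conventionally 1,000 resamples), and goodness of fit from simulation plus
a two-sided two-sample Kolmogorov–Smirnov test (`validate_fit_ks()`,
delegated to `stats::ks.test`).

A sequence of steps with *unequal* rates is hypoexponential; the
Welch–Satterthwaite moment match (`welch_satterthwaite()`) collapses a
sum of Erlang components `(k_i, θ_i)` to a single gamma with
`k_sum = (Σθ_i k_i)² / Σθ_i² k_i` and mean-matching scale. To return an
Erlang proper the shape is rounded half-up to an integer and the scale
rescaled so the mean `k·θ` is preserved exactly — rounding conventions
being otherwise arbitrary, mean preservation is the invariant we chose to
keep exact. At components `(4, 1) + (1, 3)` the KS distance between the
true convolution and the approximation is about 0.02 at 10^5 draws.

### What parameter recovery can and cannot achieve

The asymptotic variance of the shape MLE is
`1/(n(ψ′(k) − 1/k)) ≈ 2k²/n`, so at `n = 1000` the standard error of
`k̂` is about 0.36 at `k = 8` but about 2.9 at `k = 64`. Recovery of the
shape *to within one unit* is therefore essentially certain in the
few-step regime (G1, G2) and impossible to guarantee in the many-step
regime (S phase): at `k = 64` only ~40% of replicates land within ±1,
even though the median recovers `k` and the rate is recovered to a few
percent. This is a property of the statistical problem, not of the
optimizer — the relative precision of a shape estimate is fixed by
`√(2/n)` — and is the reason many-step shape estimates should always be
reported with their bootstrap spread.

## Coupling statistics

`pearson_coupling()` reports `r`, `R²`, and the two-sided p-value of the
t-test for the Pearson coefficient, and applies the decision policy used
throughout: a phase pair is *coupled* only if the correlation is both
significant (`p < 0.01`) and strong (`R² > 0.1`); significant-but-weak
pairs are labeled `weak`, everything else `uncoupled`. The policy is
applied per pair without multiplicity correction (a Bonferroni option
exists but is off by default, matching the per-pair convention). M phase
is excluded from the default pair set: at ~30 min it is comparable to the
10-min frame interval and contributes almost no variance.

Two well-known artifacts are implemented as first-class computations so
they are never mistaken for coupling:

* **Part-to-sum correlation.** Any phase correlates with the total cycle
  duration even under full independence:
  `ρ = 1/√(1 + (σ_C/σ_B)²)` for independent part B and remainder C
  (`part_sum_correlation()`). `variance_decomposition()` reports each
  phase's `R²` against the per-cell total, which for independent phases
  is just its variance share.
* **Measurement noise.** `noise_bootstrap_correlations()` recomputes the
  pair correlation under injected boundary noise
  `ε = Uniform(−0.5, 0.5)·T·δ` at each phase's begin and end (`δ = 3`
  frame-error multiplier, `T` the frame interval), independently per
  phase, per cell, per replicate, in a 100 × 100 two-level loop (10,000
  R values). "Selected without replacement with N = sample size" is
  implemented literally: every replicate uses the full dataset and all
  variability comes from the noise; a conventional with-replacement mode
  is available behind a flag. Durations pushed below zero are clamped at
  one frame and counted. Whether the noise at a shared boundary (end of
  G1 = start of S) should be shared across the adjacent phases — which
  would anti-correlate their errors — is not determined by the per-phase
  formulas; we draw independently per phase, the literal reading.

`sample_size_for_correlation()` uses the Fisher-z method with the +3
small-sample term, `n = ⌈((z_{1−α/2} + z_{power})/atanh(√R²))² + 3⌉`;
at `R² = 0.1`, two-sided `α = 0.01`, power 0.80 this gives 112 cells per
condition. The function exposes `alpha` and `power` explicitly rather
than encoding any particular labeling convention of type I/II rates. We
round up; published planning tables sometimes round to nearest, which
differs by one cell in borderline cases (e.g. `r = 0.5`, `α = 0.05`,
power 0.80: 29.01 → 30 here, 29 in tables).

## The many-for-all simulator

Per cell and phase the Erlang step rate is modulated by heritable
factors:

$$\lambda_P = \lambda_{0,P} + \gamma_P \sum_i a_{P,i}\,(n_i - \bar n_i),$$

with effect coefficients `a ~ N(0, σ = 0.01)` for every phase a factor
touches (phase-specific factors carry exactly one nonzero coefficient),
per-cell copy numbers `n_i ~ Poisson(λ_i)`, and mean abundances `λ_i`
lognormal with median 1,000 and log-sd 0.6. Durations are then direct
gamma draws `T_P ~ gamma(k_P, λ_P)` — the exact equivalent of simulating
the underlying multistep jump process, at a fraction of the cost. A
normal copy-number variant (`variance = mean`, truncated at zero and
rounded) is provided to show the results do not hinge on the Poisson
choice.

Two numerical choices deserve explanation:

* **Centering.** The factor term is centered at its ensemble expectation
  `Σ a_i λ_i`. Without centering, the random ensemble-level mean offset
  has standard deviation `σ√(Σλ_i²)` — roughly thirty-fold larger than
  the across-cell spread `σ√(Σλ_i)` at these abundances — so any `γ`
  strong enough to produce visible coupling would push most ensembles'
  rates negative. A shift common to every cell of a simulation cannot
  affect a within-population correlation, so centering preserves the
  simulated `R²` exactly while keeping duration distributions in the
  experimentally plausible regime.
* **Calibration of `γ`.** The coupling fraction is not a published
  quantity. Per phase, `γ` is set so that the expected across-cell sd of
  the factor term equals 25% of `λ_0` at the reference count
  `m_coupling = 1`, and is then held fixed when the factor count is
  swept. This yields duration CVs in the observed range at the reference
  without dominating rate negativity. Rates are floored at
  `0.05·λ_0` as a guard; at the reference calibration the floor
  essentially never fires (it does engage in the extreme `m = 1000` arm
  of the sweep, where the fixed-`γ` modulation grows as `√m`).

`coupling_sweep()` reproduces the dilution phenomenon: the mean G1–S
`R²` across simulations (200 cells each) falls monotonically as the
number of coupling factor types grows through {1, 10, 100, 1000},
reaching the sampling-noise floor (`≈ 1/n_cells`) by `m = 1000`, and
falls further when phase-specific factors are added at fixed coupling
count. `perturb_single_factor()` implements the targeted counter-
experiment: amplify ten-fold the coupling factor with the largest
product of effect coefficients on the focal pair; with the factor's
shared fluctuation now dominant, coupling reappears. Because a single
200-cell simulation estimates `R²` with substantial noise, perturbation
dominance is assessed on the across-simulations *mean* `R²` (the same
averaged quantity the sweep reports), paired by seed batch.

## Synthetic data: what it emulates, and what it does not

`simulate_phase_durations()` draws independent Erlang phases under
built-in cell-type profiles. The RPE and H9 profiles use the reported
population mean durations (RPE: 7.9/10.1/3.4/0.5 h; H9's 2.1 h G1); the
U2OS means and all shape parameters are representative package choices
inside the reported qualitative ranges (many-step S phase, `k` of order
tens; G1/G2 below 20; M phase small) — they are not measured fits, which
would require the deposited imaging data.

`apply_frame_quantization()` emulates 10-min acquisition: each event time
is snapped to the frame grid after an independent uniform within-frame
offset, so each observed event errs by at most one frame and an exact
multiple-of-frame duration can gain or lose one frame — the offsets are
per *event*, matching the independent begin/end error model of the noise
bootstrap (a single shared per-cell grid would map exact durations to
themselves and understate the error).

`simulate_sister_pairs()` generates the heritability-without-coupling
structure. Each pair inherits one Poisson copy-number vector from its
mother; each sister adds Poisson-scale jitter sized so the sister-sister
abundance correlation equals `sister_sharing` (default 0.9). Under
*independent* assortment the jitter is independent across factor types;
under the *interdependent* counterfactual one shared deviate per sister
scales all types, making abundance deviations proportional across types.
The rate map here is multiplicative,
`λ = λ_0·exp(X − sd²/2)` with `X` the standardized factor sum
(`effect_sd = 0.7` by default): at the modulation strength needed to
reproduce the strong observed sister correlations (r ≈ 0.6–0.85 at
sharing 0.9), an additive map with a rate floor generates a few percent
of twenty-fold duration outliers that destroy the very correlations
being modeled, whereas the log-scale map keeps rates positive with the
identical correlation structure. The cost is a wider duration
distribution than measured data; this generator is a harness for the
correlation structure, not a calibrated digital twin. Consequences worth
noting: per-phase sister correlations exceed 0.5 with all
sibling-difference pairs called uncoupled under independent assortment,
while interdependent assortment flips difference pairs out of
"uncoupled" — typically to "weak" (significant but `R² ≤ 0.1`), because
at sharing 0.9 only the 10% non-shared abundance variance can couple
sibling differences at all.

`simulate_reporter_trace()` builds idealized 1-D reporter signals — a
low/high/low step for the PCNA spatial-variance channel, and a
high/fall/low/ramp shape for a degron reporter — with additive Gaussian
noise and recorded ground-truth boundary frames. No functional form for
real reporter dynamics is claimed; these are constructed benchmarks for
the detectors, and passing them says nothing about segmentation or
tracking of real images (both out of scope here).

The detectors implement the standard reporter decision rules. For PCNA
variance
(`call_s_phase_pcna()`): plateau levels from the smoothed signal's tails,
boundaries at midpoint crossings sustained for ≥ 2 frames (the sustain
requirement suppresses single-frame spikes; it is this package's choice,
as a variance-transition rule alone does not dictate one). For the degron reporter (`call_phases_pip()`): S onset at
50% loss of the G1 level, G2 onset at a rise of 2% of maximum over the
S-phase level, with plateau levels estimated in two passes (provisional
crossing → refined medians → final crossing) and threshold crossings
evaluated on the *raw* signal — centered smoothing is symmetric around a
midpoint but biases near-plateau threshold crossings a frame early.
Calls are 0-based frame indices with the half-open convention (the onset
frame is the first frame inside the new phase). On 200 synthetic PCNA
traces at 5% noise, ≥ 95% of boundaries land within ±1 frame; the 2%-of-
max rule is intrinsically more fragile under noise, which is why its
noisy benchmark runs at 1% noise and the rule is otherwise validated on
exact piecewise fixtures.

## Problem sizes and reproducibility

Every stochastic function takes an explicit seed and is bit-reproducible
under it; seeds spawn deterministic child seeds where composition is
needed. The shipped checks use scaled study conditions chosen to
estimate each quantity stably: 100 seeds × n = 1000 fits for parameter
recovery; 50 simulations × 200 cells per sweep arm (the source analysis
averaged 200 simulations; 50 keeps the Monte-Carlo error of each mean
well under the arm-to-arm differences being compared); 10,000 bootstrap
replicates; 500 sister pairs; 200 traces. `scripts/acceptance.R` re-runs
the full set from scratch and writes the resulting quantities as JSON.

## Known limitations

* No censored-data likelihoods: cells whose phases are cut by the movie
  boundaries must be excluded before fitting (the ingest layer rejects
  incomplete required fields rather than modeling censoring).
* No hypoexponential fitting with free per-step rates — only its
  Welch–Satterthwaite Erlang approximation.
* The factor model is a phenomenological simulator; it is never fitted
  to data, and nothing identifies factor types with molecules.
* Shape recovery in the many-step regime is precision-limited by
  `sd(k̂) ≈ k√(2/n)`, as discussed above.
* Lineage structure is limited to mother/daughter/sister links;
  cross-generation analyses are table joins performed by the caller.
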