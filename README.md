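# erlangcycle

Erlang models and coupling statistics for single-cell cell-cycle phase
durations.

## What this package is for

Single-cell time-lapse imaging gives, per cell, five event times — birth,
S-phase onset, S-phase end, nuclear envelope breakdown, telophase — and
hence the durations of G1, S, G2 and M. Across cells each phase duration
follows an Erlang distribution (a gamma with integer shape *k*: the phase
behaves like *k* rate-limiting steps completing at rate *λ*), phases are
statistically independent of each other, and yet durations are strongly
heritable between sister cells. `erlangcycle` implements the quantitative
machinery behind these three observations, for anyone analyzing per-cell
phase-duration tables or studying models of cell-cycle progression:

* **Erlang fitting** — exact maximum likelihood under the integer-shape
  constraint: for each candidate *k* the conditional rate is closed-form
  (*λ(k) = k / mean(x)*), so the fit is a deterministic exhaustive scan
  of the profile likelihood. Includes the single-shared-rate Markovian
  variant (coordinate ascent with closed-form conditional rate),
  1,000-resample bootstrap spreads, simulation-based Kolmogorov–Smirnov
  validation, and the Welch–Satterthwaite Erlang approximation of
  hypoexponential sums:
  *k*<sub>sum</sub> = (Σθ<sub>i</sub>k<sub>i</sub>)² / Σθ<sub>i</sub>²k<sub>i</sub>,
  integer-rounded with the mean *k·θ* preserved exactly.
* **Coupling statistics** — Pearson *r*, *R*², and the t-test p-value per
  phase pair, under the decision policy *coupled ⇔ p < 0.01 and
  R² > 0.1*; the part-to-sum closed form
  *ρ = 1/√(1 + (σ<sub>C</sub>/σ<sub>B</sub>)²)* separating trivial
  part–total correlation from genuine coupling; variance decomposition of
  total cycle duration; sibling-difference coupling; a measurement-noise
  bootstrap injecting *ε = U(−0.5, 0.5)·T·δ* at each phase boundary
  (100 × 100 replicates → 10,000 R values); and Fisher-z sample-size
  planning (*R²* = 0.1, α = 0.01, power 0.80 → 112 cells).
* **The many-for-all simulator** — heritable factor types each weakly
  modulating several phase rates,
  *λ<sub>P</sub> = λ<sub>0,P</sub> + γ<sub>P</sub> Σ a<sub>P,i</sub>(n<sub>i</sub> − n̄<sub>i</sub>)*,
  with *a ~ N(0, 0.01)*, Poisson copy numbers around lognormal mean
  abundances (median 1,000, log-sd 0.6). Sweeping the number of factor
  types shows coupling diluting away; amplifying the dominant factor
  ten-fold restores it.
* **Synthetic data and trace calling** — generators for phase tables,
  frame-quantized event times, sister lineages with independent or
  interdependent factor assortment, and 1-D reporter traces
  (PCNA-variance step, PIP-degron fall/ramp), plus boundary detectors
  implementing the 50%-loss and 2%-of-max rules and an accuracy
  evaluator against ground truth.

## Worked example

```r
library(erlangcycle)

# a 125-cell table of independent Erlang phase durations (RPE-like)
tab <- simulate_phase_durations(profile_rpe(), n = 125, seed = 11)

fits <- fit_erlang_table(tab, dt = DEFAULT_FRAME_H)
fits$G1
#> Erlang fit [G1]: k = 9, lambda = 1.211 /h (mean 7.43 h), logLik = -512.679, n = 125
fits$S
#> Erlang fit [S]: k = 64, lambda = 6.274 /h (mean 10.2 h), logLik = -431.543, n = 125

all_pairwise_coupling(tab)
#>   phase_a phase_b           r          r2          p   n      call
#> 1      G1       S -0.21782160 0.047446248 0.01467794 125 uncoupled
#> 2      G1      G2  0.06126739 0.003753694 0.49729837 125 uncoupled
#> 3       S      G2 -0.12283427 0.015088258 0.17234546 125 uncoupled

nb <- noise_bootstrap_correlations(tab, pair = c("G1", "S"), seed = 12)
length(nb$r); nb$frac_uncoupled
#> [1] 10000
#> [1] 1

sample_size_for_correlation(0.1, alpha = 0.01, power = 0.8)
#> [1] 112

coupling_sweep(factor_model_params(), m_values = c(1, 10, 100, 1000),
               n_sims = 50, seed = 13)
#>      m     mean_r2       sd_r2 n_sims perturbed
#> 1    1 0.089540236 0.132051915     50     FALSE
#> 2   10 0.032817381 0.051689163     50     FALSE
#> 3  100 0.008694669 0.009732646     50     FALSE
#> 4 1000 0.004655182 0.005173740     50     FALSE
```

Reading the output: the fitted shapes recover the generating profile
(many-step S phase, few-step G1) and the mean durations; all three phase
pairs are called *uncoupled* — at n = 125, |r| ≈ 0.2 with R² < 0.1 is
exactly the regime the p < 0.01 / R² > 0.1 policy is designed to reject,
and the noise bootstrap shows the conclusion survives ±1-frame boundary
error in 100% of 10,000 replicates. The sweep shows the many-for-all
dilution: the mean G1–S R² falls monotonically as the number of
coupling factor types rises, reaching the sampling floor by m = 1000.

A shell entry point wrapping these functions (commands `fit`,
`simulate`, `couple`, `bootstrap`, `mfa-sweep`, `call-traces`, `power`)
is installed at `inst/cli/erlangcycle-cli.R`; see `?run_cli`.

## Package layout

| Area | Files |
| --- | --- |
| Phase tables, CSV schema, validation | `R/phase-table.R` |
| Synthetic generators (tables, sisters, quantization, traces) | `R/simulate.R` |
| Erlang / shared-rate / Welch–Satterthwaite fitting | `R/erlang-fit.R` |
| Coupling statistics, noise bootstrap, power | `R/coupling.R` |
| Many-for-all factor model | `R/factor-model.R` |
| Trace event detectors and evaluation | `R/traces.R` |
| Command-line entry point | `R/cli.R`, `inst/cli/` |

The methods vignette (`vignettes/cell-cycle-phase-models.Rmd`) documents
the models, the numerical choices, and what the synthetic generators do
and do not emulate.
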