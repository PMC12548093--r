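---
title: "Closed-system Rayleigh analysis of position-specific N2O isotope effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-system Rayleigh analysis of position-specific N2O isotope effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2okie)
```

## The model

An enzyme in a sealed vessel converts a finite, well-mixed pool of NO
into N₂O, two NO per N₂O. If each isotopologue reacts with first-order
kinetics and a constant rate-constant ratio, the system undergoes
Rayleigh distillation: writing R for a heavy/light abundance ratio and
f for the fraction of NO remaining, the substrate ratio evolves as
R_s = R_s0 · f^(α−1) and the *accumulated* product ratio as
R_p = R_s0 · (1 − f^α)/(1 − f), with a constant fractionation factor
α = R_instantaneous-product / R_substrate = 1/KIE.

Nobody fits those exact forms in routine practice. The field's working
equation is Mariotti's linearisation for the accumulated product,

δ_p = δ_s0 + ε · [ −f·ln f / (1 − f) ],

with ε = (α − 1)·1000 in ‰. `fit_rayleigh_linear()` performs exactly
this ordinary least-squares regression; the abscissa term is computed
by `rayleigh_abscissa()`, with its continuity limits 1 (at f = 1, the
start) and 0 (at f = 0, completion). The fit is valid for **bulk**
δ¹⁵N only — the average over the two nitrogen sites — because the N₂O
molecular-ion measurement averages the α (central) and β (terminal)
positions.

### Position-specific partition: the Expanded Rayleigh model

The per-site factors follow from two share parameters,
ρ = ¹⁵Nα/¹⁵N_bulk and τ = ¹⁴Nα/¹⁴N_bulk, through

α_Nα = (ρ/τ) · α_bulk,  α_Nβ = ((1−ρ)/(1−τ)) · α_bulk.

These relations are algebraically closed: τ·α_Nα + (1−τ)·α_Nβ =
α_bulk holds identically, and `position_specific()` preserves it to
1e-12 by construction (it is asserted on every fit in the test suite).

ρ is estimated by nonlinear least squares (`estimate_rho()`): for each
observation the bulk ¹⁵N amount is reconstructed from the measured
bulk delta by exact atom accounting, a candidate ρ allocates part of
it to the α site, and the predicted bulk delta is the mean of the
implied α-site delta and the observed β-site delta. Residuals are
therefore in bulk-δ¹⁵N space. Two structural points are deliberate,
not accidental:

* the observed bulk delta appears on both sides (it is the dependent
  variable *and* feeds the ¹⁵N_bulk predictor). That is the model's
  published form and we keep it; the alternative of iterating the
  predictor to self-consistency changes ρ̂ far below its standard
  error at natural abundance.
* τ (`estimate_tau()`) uses the measured deltas of every observation,
  averaged, rather than any fit-implied amounts — the per-observation
  definition — with SE = SD/√n and a one-sample two-sided t-test
  against 0.5.

The single-parameter least-squares problem is solved with
Levenberg–Marquardt (`minpack.lm::nlsLM`), start 0.5, bounds (0, 1),
`ftol = ptol = 1e-12`, 200 iterations maximum; with one parameter and
a smooth residual surface convergence is robust and the starting value
is immaterial in practice.

Standard errors of the per-site quantities propagate to first order
over (ρ, τ, α_bulk) treated as independent. Their covariances are not
zero in truth, but the bootstrap (below) provides the
covariance-honest alternative, and on study-like data the two agree
within rounding.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `no_initial_nmol` | 10300 | nmol | NO injected in the study design |
| `r_standard_n` | 0.0036765 | – | ¹⁵N/¹⁴N of atmospheric N₂ |
| `r_standard_o` | 0.0020052 | – | ¹⁸O/¹⁶O of VSMOW |
| `min_conversion` | 0.1 | – | Mariotti error is largest near the start |
| `plateau_fraction` | 0.01 | – | relative increment defining "production stopped" |
| `grubbs_alpha` | 0.05 | – | conventional screening level |
| `n_boot` | 1000 | – | resamples; seconds of CPU at n = 13 |

The reference-ratio constants matter only where absolute atom amounts
are reconstructed (the ρ fit); sensitivity there is weak, and both are
exposed in `n2o_config()` rather than hard-coded.

### Filters

Observations before 10% conversion are dropped (linearisation error),
and within each replicate everything from the first plateau point
onward is dropped, a plateau point being one whose cumulative-N₂O
increment over the previous sample falls below `plateau_fraction` of
its cumulative amount (a zero or negative increment always counts).
"Stopped increasing" is a judgement call in the original workflow; the
increment rule is our reproducible proxy, and it removes the first
plateau point itself as well as later ones. Every removal is logged
with its reason in the dataset's `exclusion_log`, and filtering is
idempotent. Survivors from all replicates are pooled with no
replicate-level random effect — replicates drawn from one enzyme
preparation are exchangeable by design.

f is always computed from the nominal initial NO; its measurement
uncertainty is not propagated into the regressions, matching the
ordinary-least-squares treatment of the source workflow.

### Outlier screening and bootstrap

`grubbs_one_outlier()` implements the two-sided single-outlier Grubbs
test from the t-distribution critical-value formula (no lookup
tables); at n = 10, α = 0.05 it reproduces the published 2.290. The
screening level is not fixed by the source workflow; 0.05 two-sided is
the default and configurable. The policy (`apply_outlier_policy()`)
removes at most one whole observation per pooled dataset — all delta
channels, since a flagged residual indicts the sample, not one
channel — and the default is to remove and refit, with `"flag"`
available.

`bootstrap_models()` resamples pooled observations with replacement at
the original n, unstratified. The whole resampling plan is drawn
up-front from one integer seed, so results are bit-identical across
runs and independent of evaluation order; resamples whose abscissa
collapses to a single value, or on which the nonlinear fit errors, are
counted as failed and excluded (a warning fires beyond 10% failures).
Means and SDs of KIEs, enrichment factors and both RMSE statistics are
reported.

Conventions throughout: RMSE = √(SSR/n) for both models (not
√(SSR/(n−2))); coefficient SEs use the usual OLS n−2; R² = 1 − SSR/SST
about the mean, defined as 0 (with a flag) when SST = 0; the δ¹⁸O
result is reported as a *slope*, never as ε¹⁸O, because the second
oxygen atom leaves as water and its fractionation folds into the
slope; pooled SP is summarised as mean ± SD.

## The simulator

`simulate_closed_system()` is a forward model of the assumptions
above, used for parameter recovery. Substrate consumption is
discretised into equal N₂O increments (default 10 000). At each step
the instantaneous product ratio delivered to nitrogen site j is
R_s/KIE_j; each site draws one atom per molecule from the common pool;
one oxygen atom is retained in N₂O at R_s,O/KIE_O and one leaves to
water offset by a branch enrichment factor; all bookkeeping uses exact
isotope fractions R/(1+R), and total ¹⁵N and ¹⁸O are conserved to
1e-13 nmol at every step. Gaussian noise is added only to the channels
an IRMS measures — bulk ¹⁵N (SD 0.5‰), α (0.7‰), ¹⁸O (0.5‰) — and the
β delta is then *derived* as 2·bulk − α, exactly as in real data
reduction. Its empirical SD (~1.2‰) therefore exceeds the per-channel
figure, and its noise is correlated with bulk and α; this mirrors the
measurement process and is intentional. Jitter on f is off by default.

`generate_study_like()` packages the study conditions: 10.3 µmol NO,
δ¹⁵N_s0 = −40.5‰, per-site enrichment factors −7.2‰ (α) and −9.9‰
(β), three replicates on staggered conversion grids spanning
(1−f) ≈ 0.20–0.74, 13 observations total, sampling times from the
nominal 24 nmol/min rate. The substrate δ¹⁸O is unconstrained by any
reported value and defaults to 0‰, so simulated absolute δ¹⁸O values
are not comparable to measured ones — only the slope behaviour is; the
O-atom defaults (ε retained −25‰, branch −14.8‰) average to the
observed −19.9‰ slope.

### What recovery tests do and do not show

The simulator validates the estimation chain under exactly the
assumptions the estimators make (constant KIEs, well-mixed pool, exact
stoichiometry, Gaussian IRMS noise). It does not emulate enzyme
kinetics, substrate inhibition, O exchange with water, headspace
partitioning, or drift in instrument calibration — agreement on
synthetic data says nothing about those.

One systematic deserves emphasis because it is easy to mistake for a
bug. The simulator fractionates in ratio space (constant α, the
physical assumption), but the Mariotti regression estimates the slope
of delta against the abscissa. Expanding the exact product equation
shows that slope to be ε·(1 + δ_s0/1000) plus a small curvature term:
at δ_s0 = −40.5‰ the fitted ε values are compressed by ≈ 4%, i.e.
≈ 0.3–0.4‰ for ε near −8‰, for *noise-free* data — the intercept is
unaffected. This is a property of the linearisation itself, shared by
any analysis that uses it, and it is below the ~0.5–1‰ standard errors
that IRMS noise produces at n = 13. The zero-noise recovery test in
the acceptance suite asserts the stricter 0.05‰ bound and accordingly
fails on the ε components (the intercept passes); we keep the
ratio-space simulator and report the discrepancy rather than
generating data from the linearised equation, which would hide a real
property of the method. When ε is interpreted as the operational
delta-space slope — the field's convention — the estimators are
unbiased, as the exact-Mariotti tests show to machine precision.

## Numerical choices and problem sizes

* Discretisation: 10 000 equal increments to 99.99% conversion;
  halving the step count moves sampled deltas by < 0.005‰. Recovery
  sweeps in the tests use 2 000–4 000 steps, where the discretisation
  error is still an order below IRMS noise.
* The 200-seed recovery sweep uses the full study-like design (13
  observations, standard noise); the bootstrap convergence checks use
  60–200 resamples in unit tests and 1 000 in the acceptance script.
* Degenerate inputs: identical abscissa values abort the linear fit;
  zero-spread residuals return a no-outlier Grubbs result; SST = 0
  yields R² = 0 with a flag; ties on the extreme residual take the
  first index.
* Atom accounting uses exact fractions R/(1+R) everywhere; the
  rare-isotope approximation would shift ρ by ~0.4% relative, which
  matters at the 1e-6 recovery level the tests assert.

## Known limitations

* The Mariotti-scale compression above: reported ε is the delta-space
  slope, ~4% smaller in magnitude than the ratio-space enrichment
  factor when |δ_s0| ≈ 40‰.
* The nonlinear ρ fit inherits the published model's use of the
  observed dependent variable inside its predictor; both RMSEs are
  comparable across models only in bulk-δ¹⁵N space.
* SE propagation ignores (ρ, τ, α_bulk) covariances; use the
  bootstrap SDs when that matters.
* No errors-in-variables treatment of f, no weighted regression, no
  per-replicate random effects.
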