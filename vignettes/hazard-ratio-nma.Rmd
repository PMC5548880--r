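---
title: "Bayesian network meta-analysis of correlated hazard-ratio evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian network meta-analysis of correlated hazard-ratio evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrnma)
```

## The problem

Randomised trials of first-line-plus-maintenance regimens for advanced
non-small-cell lung cancer almost always compare a regimen against standard
chemotherapy with no maintenance, rarely against each other. A network
meta-analysis connects these trials through their common comparator so that
every pair of regimens can be compared, directly or indirectly, on the two
time-to-event endpoints that matter clinically: overall survival (OS) and
progression-free survival (PFS). The evidence unit is a study-level log
hazard ratio (log HR) with a standard error, one row per (study, contrast,
endpoint); many trials report both endpoints, and those two estimates from
the same patients are correlated.

hrnma implements the full pipeline: reconstructing log HRs from partially
reported statistics, validating the evidence network, a hierarchical
Bayesian model fitted by MCMC, and the ranking/decision layer (SUCRA,
probability best, probability better than reference, league tables, and a
combined clinically-meaningful-benefit rule).

## Evidence reconstruction

Trials report efficacy in three decreasing grades of completeness, and the
package uses the best available route per row:

1. **HR with 95% CI** — `se_from_ci()`: `log_hr = ln(hr)` and
   `se = (ln hi − ln lo) / (2 z)` with `z` the exact standard-normal
   quantile (never the rounded 1.96).
2. **Two-sided log-rank p-value with event counts** — `loghr_from_pvalue()`:
   with total events `E` and comparator allocation fraction `a`, the
   observed-minus-expected information is `V = E·a·(1−a)`, so
   `|log HR| = z_p / √V` and `se = 1/√V`, signed by the reported direction.
   This is the standard indirect-estimation identity for time-to-event
   outcomes.
3. Kaplan–Meier curve digitization is out of scope here; rows derived that
   way enter as ordinary HR + CI rows.

When a row supplies both a CI and a p-value the CI wins: it carries the
directly reported precision. `provenance` records which route produced each
estimate. The p-value route is exactly invertible (`implied_pvalue()`), a
property the tests exercise to 1e-9, and is near-unbiased on simulated
exponential survival data (median reconstructed HR within 3% of truth at
500 events).

## The model

Write `y_i` for the observed log HR of estimate `i` (experimental regimen
`b` versus comparator `a`, endpoint `e(i)`, study `s(i)`), and `v_i = se_i²`
for its reported variance. The hierarchy is:

* **Consistency means.** Each regimen `k` has a basic contrast `d_{k,e}`
  versus the reference regimen (chemotherapy, no maintenance), with
  `d_{ref,e} = 0`. Any contrast is a difference of basic contrasts,
  so transitivity holds exactly (`contrast_effect()`).
* **Between-study heterogeneity.** Estimate `i` has a study-specific effect
  `δ_i ~ Normal(d_{b,e} − d_{a,e}, τ_e²)`, with an endpoint-specific SD
  `τ_e`.
* **Within-study observation model.** The vector of a study's observed log
  HRs is multivariate normal around its `δ` entries with covariance
  `Σ_jk = ρ √(s²_j s²_k)` off the diagonal and `s²_j` on it — a
  compound-symmetry block with one shared correlation `ρ` covering both
  OS–PFS pairs and multi-arm contrast pairs from the same study. The
  determinant and inverse of this block have closed forms, which the
  density evaluation uses directly.
* **Priors.**
  - `d ~ Normal(0, 10²)` on the log-HR scale: effectively flat over any
    plausible treatment effect (HR from e^-30 to e^30).
  - `τ_e ~ Uniform(0, τ_max)` with `τ_max = ln(2)/z_{0.975} ≈ 0.354`. The
    calibration: at the prior's upper endpoint, 95% of study-specific
    relative efficacies lie within a factor of two of the mean contrast —
    `2Φ(ln 2/τ_max) − 1 = 0.95` exactly, which the tests assert
    analytically.
  - `s²_i ~ InverseGamma(α_i, β_i)` with the mean pinned to the reported
    variance, `β_i/(α_i−1) = v_i`, and concentration driven by the event
    count. The default reading (`ig_mode = "inverse_events"`) sets
    `α_i = 2 + n_events`, so better-reported studies get tighter priors
    around their reported variance — the statistically coherent direction.
    A literal alternative (`"literal_events"`, `α_i = 2 + 1/n_events`,
    prior variance growing with events) is available as a configuration
    switch for sensitivity analysis; which reading a given analysis wants
    is genuinely ambiguous, so both are first-class.
  - `ρ ~ Uniform(0, 0.95)`.

States outside the prior support evaluate to `-Inf` in `log_posterior()`
rather than raising: the sampler treats them as ordinary rejections.

OS and PFS share the network topology and `ρ` but have independent `d` and
`τ` per endpoint. A regimen can be estimable for one endpoint only; each
endpoint's sub-network is restricted to the component connected to the
reference (`endpoint_subnetwork()`), and regimens outside it are reported
as missing for that endpoint rather than being silently extrapolated.

## Sampling

`fit_nma()` runs an adaptive Metropolis-within-Gibbs sampler (compiled
core). Scalar random-walk updates touch each basic contrast, study effect,
and within-study variance (log scale); `τ` and `ρ` move on logit-transformed
scales of their ranges with Jacobian corrections, which avoids boundary
sticking near 0. One further move type is needed for correctness at the
edges of the prior: a joint *translation* that shifts a basic contrast
`d_j` and all its adjacent study effects by the same signed amount. When
`τ` is small, `d` and `δ` are nearly deterministically coupled and
one-at-a-time updates mix at rate `τ`; the translation move leaves the
random-effects residuals invariant and samples `d` against the observation
blocks directly. All proposals are symmetric and step sizes adapt toward a
30% acceptance rate during burn-in only, so the retained draws come from a
fixed kernel.

Chain `c` is seeded `base_seed + c`; identical inputs and seeds give
bit-identical draws. Defaults are desk-scale — 4 chains, 2,000 burn-in,
5,000 retained draws — chosen so that the small networks in the examples
and the simulation studies below run in about a second per fit while
leaving bulk ESS in the hundreds for every parameter. Full-fidelity runs
(for instance 10 chains of 100,000/100,000) are one `sampler_config()` call
away. Convergence is summarised per parameter by split-chain R-hat and a
Geyer-truncated bulk effective sample size (`mcmc_diagnostics()`); the fit
is flagged converged when every R-hat is below 1.01.

```{r, eval = FALSE}
net <- fixture_suite()$two_endpoint
fit <- fit_nma(net, sampler = sampler_config(base_seed = 1))
glance(fit)
tidy(fit)
```

## The reporting layer

Per endpoint, every retained draw ranks the regimens by their basic
contrast (lowest log HR = rank 1 = best; exact ties, a measure-zero event,
break deterministically by regimen id). From the rank matrix:

* `sucra()` — the average of the cumulative probabilities of being ranked
  best, top two, top three, …: 1 means certainly best, 0 certainly worst,
  and the values always sum to half the number of regimens.
* `prob_best()` — the first rank column; `prob_better()` — the fraction of
  draws with contrast below zero.
* `hr_summary()` / `league_table()` — exponentiated posterior medians with
  equal-tailed credible intervals, for basic and all pairwise contrasts.
  The median is used as "the HR" throughout because it is equivariant
  under the log/exp transform and under reciprocals, which is what makes
  league tables exactly reciprocal-symmetric; published tables rarely say
  whether they print medians or means, and the median is the robust
  choice.
* `combined_benefit()` — the decision rule: flagged iff the posterior
  median HR is ≤ 0.80 **and** the probability of beating the reference is
  ≥ 0.95, on both OS and PFS (both inequalities inclusive; an HR around
  0.80 is the conventional threshold for a clinically meaningful effect in
  this disease). Regimens missing an endpoint are "not evaluable" and
  never flagged.

## The generator, and what passing tests do and do not show

`simulate_network()` draws evidence from the model's own generative
process: a spanning tree of contrasts guarantees connectivity, extra
contrasts are random; event counts are uniform on a configurable range
(default 50–300, the order of magnitude of the phase-III trials this
evidence base contains); within-study variances follow the 1:1-allocation
identity `v = 4/events`; study effects get between-study SD 0.15 (a
moderate heterogeneity on the log-HR scale); paired OS/PFS errors are
correlated at 0.5 by default. Spanning-tree studies always report both
endpoints so that each endpoint's sub-network stays connected; other
studies report one or two endpoints with configurable probabilities, as in
real evidence bases. A `degrade_fraction` of rows is emitted as p-value +
events only, exercising the reconstruction path end-to-end.

Because the generator *is* the model, parameter-recovery results validate
the implementation, not the model's adequacy for real data. Real evidence
bases add features the generator does not emulate: publication bias,
systematically misreported variances, non-proportional hazards,
inconsistency between direct and indirect evidence (no node-splitting
assessment is provided), and subgroup labels that are only as good as the
underlying biomarker assays. The calibration study (100 networks of 12
studies and 4 regimens, fitted at desk scale) shows empirical 95%-interval
coverage near 97–98% rather than 95%: with only a dozen studies `τ` is
weakly identified and the hierarchical model honestly propagates that
uncertainty into wider contrast intervals. That conservatism is a property
of the model at small study counts, not a defect of the sampler — the
quadrature cross-check below pins the sampler itself to the exact
posterior.

## Numerical choices

* Compound-symmetry observation blocks use the closed-form determinant and
  inverse; positive definiteness across `ρ ∈ [0, 0.95)` is verified against
  Cholesky in the tests.
* The R-level `log_posterior()` is the single reference density; the
  compiled sampler's density agrees with it to 1e-10 on randomized states
  (tested), so the fast path cannot drift from the documented model.
* Sampler correctness is established by three independent oracles: a
  conjugate normal limit (inverse-gamma concentration → ∞, `τ_max` → 0), an
  inverse-variance pooling limit with two studies, and brute-force
  quadrature of the identical joint density on a three-regimen loop
  (marginal means within 0.02 log-HR, SDs within 5%).
* Degenerate inputs fail loudly at ingest: zero-width or inverted CIs,
  non-positive HRs, p = 0, duplicated (study, contrast, endpoint) rows,
  and disconnected networks are all errors that name the offending rows or
  components.

## Limitations

No node-splitting inconsistency assessment, no meta-regression on
covariates, no arm-level likelihoods (evidence enters as contrast-level
log HRs), and no reconstruction from digitized survival curves or median
survival times. Subgroups are analysed as fully independent networks; no
information is shared across them.
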