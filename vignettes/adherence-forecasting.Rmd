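---
title: "Sequential modelling of SCIT adherence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential modelling of SCIT adherence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the synthetic-cohort generator, the
numerical choices and the known limitations of `scitseq`. It states no
empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## Data model

A cohort lives on a fixed visit grid, by default months 0, 4, 12, 18, 24
and 36 (`time_grid()`), with deliberately uneven intervals: clinical
follow-up is front-loaded during buildup and early maintenance. Per
patient and visit there are eleven scores `x_t` — ten VAS symptom
severities on 0–10 (nasal itching, sneezing, rhinorrhea, nasal
congestion; ocular itching, lacrimation; shortness of breath, chest
tightness, cough, wheezing) and one cumulative rescue-medication score —
plus a per-interval binary adherence flag `y_t` and action `a_t`, with
`a_t = y_t` numerically: in this observational setting "treatment given
over the interval" and "patient adhered over the interval" coincide, but
the two are kept distinct in the interface so richer action spaces remain
possible. Fourteen static features `s` are recorded at enrolment; the
data dictionary names thirteen interpretable ones (age, gender, commute
distance, cost/family-income ratio, eosinophil count and percentage,
nasal-provocation ΔNR% and ΔPNIF%, total IgE, Der p/Der f sIgE, Der p/Der
f skin-prick indices) and labels the fourteenth slot `reserved`; the
generator fills it with uninformative noise and downstream attributions
treat it like any other feature.

Three structural invariants are enforced on every cohort and rejected
with classed errors otherwise: the first interval is adherent for every
patient (enrolment requires completing the 4-month buildup), dropout is
absorbing, and `y = a` everywhere. Post-dropout visits remain *observed*:
the record system tracks every patient through month 36, so sequences are
complete and untreated intervals are encoded by `a_t = 0` rather than by
a missingness mechanism. Scores are therefore modelled for all patients
at all visits.

## The sequential latent-variable model

The SLVM is a single-level Gaussian state-space model with filtering
inference — the generative backbone of stochastic latent actor-critic
architectures, used here purely as a generative model (no actor, no
critic, no policy optimisation). Conditionals, all one-hidden-layer tanh
networks of width `hidden_width` (default 64) over a latent state of
dimension `latent_dim` (default 16):

* `p(z₁ | s)` and `p(z_{t+1} | z_t, a_t, Δt_t, s)` — diagonal Gaussians;
* `p(x_t | z_t)` — diagonal Gaussian with a learned per-dimension
  variance shared across time;
* `p(y_t | z_t)` — Bernoulli, decoded from the latent state rather than
  from decoded scores, making `z_t` the sufficient statistic for
  adherence risk;
* `q(z₁ | x₁, s)` and `q(z_{t+1} | z_t, x_{t+1}, a_t, Δt_t, s)` —
  filtering posteriors (no smoothing: predictions at step `t` may only
  use information available at step `t`).

Design choices where the architecture was genuinely open:

* **Where `s` enters.** Static features condition the initial prior, the
  transition and both posteriors by concatenation. `s` is known at
  enrolment, so every conditional may legitimately see it; routing it
  everywhere lets the model decide where it matters, and lets feature
  attribution reach adherence predictions through the posterior path.
* **Uneven intervals.** The interval length `Δt` (months, scaled by
  1/12) is appended to transition and posterior inputs
  (`interval_feature = TRUE`). The final 12-month interval behaves
  differently from the 4–6-month ones, and a time-homogeneous transition
  would conflate them.
* **Log-variances** are soft-bounded to (−5, 5) by `5·tanh(·/5)`: smooth,
  differentiable, and it prevents the overconfidence spiral (variance →
  0, precision-weighted errors → ∞) that destabilises small-data
  variational training. The bound is generous — sd between ~0.08 and
  ~12 in normalized units.
* **Adherence threshold** is 0.5, ties classified as adherent.

Training maximises
`ELBO = Σ_t E_q[log p(x_t|z_t)] + Σ_{t<T} E_q[log p(y_t|z_t)] − β Σ_t KL(q_t ‖ prior_t)`
with a single reparameterized sample per step and patient, full-batch
Adam by default, `β = 1` with no annealing. The KL at each step is the
closed-form divergence between the posterior and the transition prior
evaluated at the *same* sampled `z_{t−1}`. The test suite pins the ELBO
against an independently coded closed-form oracle on 1-D latent toy
instances (tolerance 1e−5) and checks the KL's non-negativity on every
training step.

Everything runs on a small tape-based reverse-mode autodiff engine over
dense matrices written for this package (about a dozen primitives:
matmul, broadcast add, tanh/sigmoid/exp/softplus, slicing,
concatenation, Gaussian/Bernoulli log-likelihood and KL reductions). Its
gradients are validated against central finite differences. This keeps
the dependency footprint to base R and makes input gradients — needed for
integrated gradients — a one-liner.

### Prediction protocols

*One-step*: filter to step `t` with `n_latent_samples` particles (default
100), decode `y_t` from each particle, propagate each particle once
through the transition prior with the **observed** action `a_t` and
decode `x_{t+1}`. Reported point predictions are particle means;
sampling spread is the particle standard deviation; scores are reported
on both normalized and raw VAS scales (metrics use the raw scale —
error bands are only meaningful in VAS units).

*Rollout*: filter to the start step, then propagate only the transition
prior. Future actions are the model's own thresholded adherence
predictions, per particle, and absorbing: once a particle predicts
discontinuation, its subsequent injected actions stay 0, mirroring the
domain invariant. No future observation is consumed.

*Counterfactual contrast* (`action_contrast()`): filter once through the
three-visit prefix, then roll the *same* particles forward under forced
all-treated and all-untreated action sequences with common random
numbers, so the two arms differ only through the actions; the contrast is
the difference in predicted final-visit scores, reported primarily in
normalized units with a raw-scale companion and a patient-level
percentile bootstrap. Swapping the arms negates the contrast exactly;
identical arms give exactly zero. The contrast is defined for the SLVM
only — the LSTM has no generative state to roll forward under exogenous
actions and raises a capability error.

*Feature attribution* (`cohort_importance()`): integrated gradients of
the adherence probability at a target step (default 2, the first step
whose labels are not degenerate) with respect to the normalized static
features, holding the patient's scores and actions fixed. The attributed
function propagates posterior *means* (no sampling), keeping it smooth
and deterministic. The baseline is the all-zeros vector in normalized
space — the training-cohort mean patient — and cohort aggregation is the
mean absolute attribution; both are configurable. The right-Riemann path
approximation satisfies completeness up to a discretisation error that
the tests bound at 1e−2 for `m = 256` and verify is monotonically
refined.

## The LSTM baseline

A single-layer LSTM over inputs `[x_t, y_{t−1}, s, Δt_t]` with `y₀ := 1`
(every patient enters under treatment) and two linear heads: next scores
(normalized scale, squared-error loss) and current adherence (logit,
cross-entropy weighted by `λ`, default 1). `s` is concatenated at every
step. Rollouts feed predictions back autoregressively, thresholding the
adherence feedback at 0.5 (and absorbing), keeping the fed-back inputs
binary like the training data. The model is deterministic at prediction
time; uncertainty is carried by cross-validation folds only, whereas the
SLVM adds latent-sampling spread (the 100-sample protocol applies to the
probabilistic model alone).

## The synthetic-cohort generator

No public version of the reference hospital cohort exists, so the
generator is the package's test bed. It emulates, loosely and
documentedly, the cohort's structure rather than its joint distribution:

* **Statics**: age from a child/adolescent/adult mixture (47/15/38%),
  gender Bernoulli(0.7), commute distance lognormal with P(≤10 km) ≈
  0.66, cost/income lognormal, heavy-tailed lognormal laboratory values
  (eosinophils, ΔNR%, ΔPNIF%, total IgE, sIgE and SPT indices around the
  reference medians), `reserved` standard normal.
* **Dynamics**: three latent symptom-group severities (nasal, ocular,
  pulmonary; nasal/ocular initialised highest, matching the dominant
  phenotype). Over a treated interval of `Δt` months severity is
  multiplied by `exp(−treatment_effect·Δt)` (default 0.06/month ≈ 90%
  reduction over the full course); over untreated intervals it drifts up
  by `rebound_rate·Δt` (default 0.12 VAS/month, capped at 10). Each
  symptom score is its group severity plus Gaussian noise (sd 0.8),
  clipped to [0, 10]. The medication score is a monotone step function of
  total severity into {0..7}, mirroring the cumulative point scheme
  (antihistamines 1, local glucocorticoids 2, oral glucocorticoids 3).
* **Dropout**: first interval forced adherent; thereafter a per-interval
  logistic hazard on standardized log-distance, cost ratio, current total
  severity, fractional improvement since baseline, and elapsed time, with
  per-interval intercepts. The default intercepts are calibrated so the
  205-patient preset reproduces the reference withdrawal pattern — the
  conditional dropout probabilities implied by the published
  reason-by-period table (35/205, 26/170, 14/144, 57/130), i.e. ~64%
  cumulative non-adherence with the heaviest mass in the final year.
  (The same publication elsewhere prints 35.4% as the "total
  non-adherence rate"; its own tables and discussion identify 35.4% as
  the *accomplishment* rate, and the generator follows the tables.)

Two diagnostic presets support recovery experiments: `preset_separable()`
makes dropout an almost deterministic function of commute distance alone
(planted-signal recovery for classification and attribution), and
`preset_null_effect()` removes the treatment effect entirely (null
recovery for the counterfactual contrast). Ground truth — severity paths
and realized hazards — is returned alongside every cohort.

What passing tests on this generator do **not** show: real SCIT cohorts
have informative missingness, reporting artefacts, within-group symptom
heterogeneity, co-varying reasons for withdrawal (the generator has a
single hazard, not competing reasons), and action spaces richer than a
binary flag. Benchmarks here demonstrate that the machinery recovers
planted structure under its own assumptions, not clinical performance.

## Evaluation protocols

The experiment design mirrors the reference analysis: 20% of patients
form a fixed test set (41 of 205 at the study size), the remainder is
partitioned into five folds, and per-fold models yield mean ± sd metric
bands; normalization statistics are always fit on training patients only
(a leakage property test rewrites the test patients and asserts the
statistics are unchanged). Scores are judged by RMSE on the raw VAS scale
(overall and per dimension), adherence by accuracy/precision/recall/F1
with *adherent* as the positive class — at step 1 every label is
positive, so that row is flagged degenerate and trivially scores 1.00.
Undefined precision (no predicted positives) is reported as 0 with a
warning. Uninformed baselines are uniform draws on each dimension's
observed range for scores (closed forms: √(100/6) ≈ 4.082 against uniform
truth on [0,10], 10/√3 ≈ 5.774 against truth pinned at zero) and a fair
coin for adherence. The fold statistic reported is across folds only; the
alternative folds × samples pooling for the probabilistic model is left
to the caller via the per-prediction spreads.

## Numerical choices and problem sizes

Normalization uses population (1/n) standard deviations, making the
transformed training sample exactly unit-sd; constant dimensions fall
back to sd 1 with a warning. Percentage tables round half away from
zero to one decimal, matching clinical-table convention; quantiles are
type-7 (linear interpolation). Training aborts with a component-named
error on non-finite objectives. Test-suite problem sizes were chosen to
exercise every claim at desk scale: benchmark cohorts of 1000 patients
(800 training), latent dimension 8, width 32, 100–200 epochs, five
seeds; the generator's marginal-consistency check runs at n = 100 000.

## Known limitations

* The SLVM is single-level; a two-level latent factorisation is left as a
  config extension point.
* `y = a` ties adherence to treatment; counterfactual contrasts are
  model-consistency probes, not causal estimates — no identification
  claims are made.
* Whether the original architecture conditioned its adherence head on `s`
  directly is unknown; here `s` reaches adherence only through the
  posterior, which the attribution results show is sufficient to recover
  static-feature signal.
* The attribution target (step, output) is configurable because the
  reference figure does not state one; the default (adherence at step 2)
  is the earliest unbiased choice.
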