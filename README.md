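# scitseq

Sequential models for forecasting patient adherence and symptom scores
during multi-year subcutaneous allergen immunotherapy (SCIT).

## The problem

SCIT for house-dust-mite allergic rhinitis is a three-year course of
clinic-administered injections. A large fraction of patients discontinue
before completion, and both the *when* and the *why* matter clinically:
a model that can flag imminent non-adherence at any follow-up visit lets
the care team intervene early, and a model that can simulate a patient's
trajectory under treated versus untreated futures tells the clinician how
much adherence is worth for that particular patient.

The data are short, irregularly sampled clinical time series: at visits
scheduled at months 0, 4, 12, 18, 24 and 36 each patient reports ten
visual-analogue-scale (VAS) symptom scores (nasal, ocular and pulmonary,
each on 0–10) plus a cumulative rescue-medication score, giving a score
vector `x_t ∈ R¹¹`; each inter-visit interval carries a binary adherence
flag `y_t` (1 = continued treatment) that doubles as the treatment action
`a_t`; and each patient has 14 static baseline features `s ∈ R¹⁴`
(demographics, commute distance, financial burden, laboratory and
sensitization measurements). The first interval is always adherent —
enrolment requires completing the 4-month buildup — and dropout is
absorbing.

## The models

**Sequential latent-variable model (SLVM).** A Gaussian state-space model
with a latent patient state `z_t`:

- initial prior `p(z₁ | s)` and transition prior
  `p(z_{t+1} | z_t, a_t, Δt_t, s)` (the interval length `Δt` is an input
  because the visit grid is uneven);
- score decoder `p(x_t | z_t)` (diagonal Gaussian, learned variance) and
  adherence decoder `p(y_t | z_t)` (Bernoulli);
- filtering posteriors `q(z₁ | x₁, s)` and
  `q(z_{t+1} | z_t, x_{t+1}, a_t, Δt_t, s)`.

All conditionals are one-hidden-layer tanh networks. Training maximises
the evidence lower bound

```
ELBO = Σ_t E_q[log p(x_t | z_t)] + Σ_{t<T} E_q[log p(y_t | z_t)]
       − β Σ_t KL(q_t ‖ prior_t)
```

with single-sample reparameterized gradients. One-step prediction filters
the posterior to step `t` and decodes `y_t` and `x_{t+1}` from latent
samples; multi-step *rollouts* propagate only the transition prior,
injecting the model's own thresholded adherence predictions as future
actions. Because the model is generative over actions and states, it also
serves as a patient simulator: the counterfactual contrast compares
rollouts under forced all-treated vs all-untreated action sequences with
common random numbers, and integrated gradients attribute adherence
predictions to the 14 static features.

**LSTM baseline.** A single-layer LSTM consuming `[x_t, y_{t−1}, s, Δt_t]`
per step predicts `x_{t+1}` and `y_t` in parallel through two heads
(squared error + weighted cross-entropy), with autoregressive feedback for
rollouts. It is deterministic; its uncertainty comes from cross-validation
folds only.

Both models run on a small reverse-mode automatic-differentiation engine
included in the package (dense matrix ops, checked against finite
differences in the test suite), so no deep-learning runtime is required.

The hospital cohort behind the reference analysis is not publicly
available, so the package ships a seeded synthetic-cohort generator that
emulates its structure — latent symptom-group severities that decay under
treatment and rebound after discontinuation, heavy-tailed laboratory
marginals, and a covariate-dependent logistic dropout hazard whose preset
reproduces the reference cohort's withdrawal pattern (about 64%
non-adherence over three years, heaviest in the final year) — together
with its ground truth for recovery experiments.

## Worked example

```r
library(scitseq)

gt <- generate_cohort(preset_study_like(seed = 7))
co <- split_cohort(gt$cohort, test_fraction = 0.2, k_folds = 5, seed = 7)
co
#> <scit_cohort> 205 patients, 6 visits at months 0/4/12/18/24/36
#>   cumulative non-adherence by final interval: 62.9%
#>   split: 41 test, folds {33,33,33,33,32}

model <- slvm_fit(co, slvm_config(latent_dim = 8, hidden_width = 32,
                                  epochs = 150, learning_rate = 1e-2,
                                  seed = 7))
pred <- predict_one_step(model, co, t = 2, patients = test_idx(co), seed = 7)
mean(pred$y_prob)                                  # 0.837
mean(co$y[test_idx(co), 2])                        # 0.805 observed
rmse(pred$x_mean_raw, co$x[test_idx(co), 3, ])     # 0.80 VAS units
random_baselines(co, seed = 7)$rmse_uniform[2]     # 3.84 (uninformed)

action_contrast(model, co, seed = 7)
#> <scit_contrast> final-visit score difference, treated - untreated
#>   mean (normalized units): -2.225  [bootstrap 95%: -2.320, -2.138]
#>   mean (VAS units): -4.182
```

The one-step score error (0.80 VAS units on a 0–10 scale) is far below
the uninformed uniform-random baseline (3.84), and the counterfactual
contrast recovers the generator's planted treatment benefit: staying on
treatment lowers the predicted final-visit scores by about 4.2 VAS points
on average.

Descriptive statistics of the reference cohort's printed withdrawal table
(bundled as a transcribed fixture):

```r
rates <- withdrawal_rates(withdrawal_table(
  system.file("extdata", "table2.csv", package = "scitseq")))
rates$year
#> year1 year2 year3
#>  26.5  30.3  43.2
```

`run_pipeline()` chains every stage — simulate, split, train, evaluate
(one-step and rollout), counterfactual, importance, summarize — into one
seeded, manifest-tracked artifact directory.

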