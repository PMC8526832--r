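---
title: "Deep Bayesian Gaussian processes for clinical sequence risk prediction: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep Bayesian Gaussian processes for clinical sequence risk prediction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Risk models built on longitudinal health records usually emit a point
probability: *this patient has a 12% chance of developing heart failure
within six months*. For clinical use the missing quantity is how much the
model itself is uncertain about that number — whether the 12% rests on
thousands of similar training patients or on extrapolation. `bgpseq`
implements a family of models that attach a predictive *distribution* to
each patient, and an evaluation suite that asks whether the resulting
uncertainty is informative: do the model's mistakes carry visibly more
uncertainty than its correct calls?

## Model family

All variants share one feature extractor `g(x, w)`: a BEHRT-style
transformer over sequences of clinical code tokens. Each encounter is
embedded as the sum of four lookup tables — code, age in integer years,
visit-parity segment (alternating 0/1 per visit), and visit-rank position
— followed by layer normalisation, a stack of post-norm self-attention
layers, and a tanh-pooling of the first (CLS) position. Six classifier
configurations sit on top of the pooled vector:

* **BE / BO / BE+BO** — a linear logistic classifier; the embedding
  tables and/or the classifier weights carry mean-field Gaussian
  posteriors `q(w) = N(mu, softplus(rho)^2)` trained by Bayes by
  Backprop against a `N(0, 0.374^2)` prior.
* **SPARSE_GP** — a sparse variational GP classifier with 40 free
  inducing points and an RBF kernel over the pooled space, whitened
  variational distribution with `N(0, I)` prior, Bernoulli likelihood
  via Gauss–Hermite quadrature (order 20).
* **KISS_GP** — structured kernel interpolation: inducing points
  constrained to a fixed 1-D grid per pooled dimension, cross-covariances
  approximated by local linear interpolation onto the two adjacent grid
  points, one additive kernel per dimension.
* **DBGP** — the hybrid: stochastic embeddings *and* the KISS-GP head,
  so predictive uncertainty has both a weight-space and a function-space
  source.

Predictive inference is Monte Carlo: `S = 30` weight draws, each fixing
the stochastic tables and computing the patient's probability (for GP
heads, marginalising the latent with quadrature). The per-patient mean
is the risk estimate; the per-patient standard deviation is the
predictive uncertainty.

### Why a per-dimension additive grid for KISS

A tensor-product grid over a 24-dimensional (or even 8-dimensional)
pooled space is astronomically large; the interpolation idea only bites
in low dimension. We therefore give each pooled dimension its own 1-D
grid and kernel and sum the per-dimension latent functions. Because the
pooled features are tanh outputs, they live in (−1, 1); the default grid
spans [−1.1, 1.1], so queries never fall outside it (out-of-range
queries are clamped with a warning). In the whitened parameterisation
the interpolated cross-covariance gives `a_i = L' W e_i` with `W` sparse
(two entries per row), so no dense kernel matrix over the data is ever
formed.

### Objective and its scaling

Each minibatch objective is the negative of

    (N/B) * sum_i E_q[ log Bernoulli(y_i | pi(f_i)) ]
      − (1/M) * KL( q(f_m) || N(0, I) )
      − pi_b  * KL( q_gamma(w) || p(w) ),

where `pi_b = 2^(M−b)/(2^M − 1)` is the Blundell minibatch weight
(summing to one over an epoch) applied to the weight-KL only; the GP KL
is spread uniformly over the `M` batches. Both conventions integrate to
the exact evidence lower bound once per epoch; how the two KL terms are
jointly scaled within a batch has no single established convention, so
this is recorded as a package decision. One weight draw is used per training step, 30 at
inference.

All gradients are analytic and hand-derived (reverse mode through the
transformer, the reparameterised posteriors, the interpolation weights,
and the Cholesky factorisations via the standard adjoint); the test
suite checks every parameter group against central finite differences.

## Training at desk scale

The full-scale hyperparameters (Adam, learning rate 3e-5, weight decay
0.01, batch 64) are tuned for cohorts of ~10^6 patients and are kept as
the defaults of `training_config()`. The package's own experiments run
at a few thousand patients, where two facts dominate:

1. At `n ≈ 1000` the weight-KL term is of the same order as the data
   term (thousands of stochastic weights), so a cold-started
   stochastic-embedding model rationally collapses to the base rate
   while its posterior widens toward the prior. The remedy is the usual
   warm start for Bayesian networks: fit a deterministic-encoder model
   first and copy its weights in as the variational means
   (`init_from_pretrained()`, wrapped by `fit_variant()`); classifier
   heads are freshly initialised.
2. Embedding tables are initialised at scale 0.3 and transformer
   weights at 0.1. The embedding scale is forward-invariant (layer
   normalisation follows the embedding sum) but sets the signal-to-noise
   ratio of weight draws; the transformer scale determines how quickly
   token information reaches the pooled CLS position on short optimisation
   budgets.

`desk_training_config()` (learning rate 3e-3, head 1e-2) and
`desk_encoder_config()` (hidden 16, 2 layers, 2 heads, pooled size 8,
grid 32/dimension) define the scale used throughout the tests: cohorts
of 2000 patients split 50/20/30 into train/tune/validation, 20 warm-up
plus 10 fine-tuning epochs. `paper_encoder_config()` preserves the
full-scale architecture (hidden 150, 4 layers, 6 heads, intermediate
108, dropout 0.29, maximum length 256, pooled 24 for GP heads).

## The synthetic cohort generator

Real primary-care datasets are license-restricted, so the package ships
a generator that emulates the *structure* the models consume: 3–6
visits per patient, 2–4 uniformly drawn surrogate codes per visit,
ages starting uniform in 40–70 and advancing 0–2 years between visits,
alternating segment ids, visit-rank positions, and a CLS/SEP token
skeleton. Outcomes follow a planted log-odds process:

    logit P(y=1) = b + sum of effects of risk tokens present + N(0, 0.5^2)

with the intercept `b` tuned by root finding so the expected positive
fraction hits the target rate (default 10%, inside the 8–16% range of
first-incidence chronic-disease cohorts). The Gaussian log-odds noise
makes the Bayes-optimal AUROC well below 1, so both reducible and
irreducible error exist. The default effects (+4, +3, +2 on three
tokens of ~15% prevalence each) are deliberately strong, in the way
that diuretics predict heart failure: they create a small subgroup
whose true risk exceeds the 0.5 decision threshold, without which the
TP/FP uncertainty comparison that motivates the package would have no
predicted positives to examine.

What the generator does **not** emulate: real code frequency
distributions (codes are uniform), code co-occurrence structure,
calendar time and inter-visit gap patterns, and any selection funnel.
Passing tests therefore demonstrate that the machinery works and that
the uncertainty diagnostics behave as designed on data with planted
structure — not that the model is clinically adequate.

## Evaluation suite

* **Ranking**: AUROC (midrank Mann–Whitney form) and average precision
  on the mean predictive probability, with 95% percentile intervals
  from 50 seeded patient-level bootstrap resamples.
* **Rejection curves**: confidence is `max(p, 1−p)`; at each threshold
  the retained subset's accuracy (and AUROC where both classes survive)
  is reported. A probability of exactly 0.5 counts as a negative
  prediction.
* **Calibration with epistemic bands**: every MC draw is treated as an
  independent model; each contributes a 10-bin calibration curve, and
  the 2.5/97.5 percentiles across draws form the band. The per-sign
  band-width summary weights bins by occupancy.
* **DIV**: within each prediction sign, Gaussians are fitted (sample
  mean, n−1 sd) to the predictive sds of incorrect (F = FP or FN) and
  correct (T = TP or TN) predictions and `KL(N_F || N_T)` is returned
  in closed form, in nats. The direction F‖T follows the defining
  equation of the statistic. Cells with fewer than two members or zero
  variance yield `NA` with a reason code rather than an error.
* **Embedding entropy**: for stochastic embeddings, each code token is
  scored by `sum_d 0.5 ln(2 pi e sigma_d^2)` over its posterior row and
  ranked ascending — low entropy marks codes whose association with the
  outcome the model considers settled. Natural logarithms throughout;
  special tokens are excluded.

## Numerical choices

Cholesky factorisations carry 1e-6 jitter (escalating with a warning if
needed); latent variances are floored at 1e-10; Gauss–Hermite order is
20 everywhere; layer-norm epsilon is 1e-6; attention masking uses an
additive −1e9 before the softmax. Sequences longer than `max_seq_len`
raise an error unless clipping from the sequence start (retaining CLS)
is explicitly enabled. All randomness flows from explicit seeds through
deterministic stream derivation, so cohorts, training runs and MC
predictions reproduce bitwise; repeated pipeline runs with one seed
produce byte-identical reports.

## Known limitations

* The desk-scale experiments use a single shared RBF lengthscale per
  head (per dimension for KISS); ARD lengthscales are not implemented.
* Masked-language-model pre-training is exposed only as the
  `init_from_pretrained()` hook; no self-supervised objective ships with
  the package.
* The KISS head's O(N) Toeplitz/Kronecker algebra is not implemented —
  at desk scale, direct sparse-times-dense products are faster than the
  asymptotic machinery would be.
* DIV is reported separately per prediction sign; pooling both signs is
  available by concatenating cells but is not the default.
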