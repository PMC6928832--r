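---
title: "Selective ensembles for gas-sensor-array diagnostics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective ensembles for gas-sensor-array diagnostics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Electronic noses measure a breath sample as the joint transient response of
an array of non-selective chemical sensors — by default here, 13 channels
sampled at 675 points each, i.e. an 8775-dimensional vector per subject.
Screening applications (distinguishing disease-positive from healthy breath)
put a premium on *sensitivity*: a missed positive is far more costly than a
false alarm. This package implements a full pattern-recognition pipeline for
such data: unsupervised feature extraction with a recurrent sequence
autoencoder, an overproduced pool of bagged decision trees, and — the core of
the package — *ordering-based ensemble pruning* driven by voting-margin
theory, with a sensitivity bonus that explicitly rewards classifiers that get
positive samples right.

```{r setup}
library(msep)
library(dplyr)
```

## Voting margins

For a pool $H = \{h_1,\dots,h_M\}$ of binary classifiers and a pruning sample
$(x_i, y_i)$, the margin is the fraction of correct votes minus the fraction
of incorrect votes,

$$\mathrm{margin}(x_i) = \frac{\sum_j I(h_j(x_i)=y_i) - \sum_j I(h_j(x_i)\ne y_i)}{M} \in [-1, 1],$$

which is never exactly 0 when $M$ is odd. It measures the confidence of the
pool's majority decision: a large positive margin means a confidently correct
ensemble, a negative margin a sample the majority gets wrong. Margin theory
ties large margins over the training distribution to better generalisation,
which motivates scoring individual classifiers by how much they contribute to
correct decisions on *low-margin* (hard) samples. Writing
$\mathrm{NF}_i = \sum_j I(h_j(x_i)\ne y_i)/M$ for the pool-wide incorrect
fraction, the identity $\mathrm{margin}(x_i) = 1 - 2\,\mathrm{NF}_i$ holds
exactly and is asserted in the test suite.

## The pruning measures

All four measures consume the same substrate: the binary *vote matrix* with
entry $(i,j) = I(h_j(x_i) = y_i)$ over the pruning set, produced by
`compute_vote_matrix()` or simulated directly by `simulate_vote_matrix()`.

**MSM** (margin and sensitivity based measure), the package's centrepiece,
marks classifier $h$ as

$$\mathrm{MSM}(h) = \frac{1}{N_{Pr}} \sum_i I(h(x_i)=y_i)\; I(\mathrm{margin}(x_i) > \theta)\; e^{y_i \mathrm{NF}_i}\; e^{-\mathrm{margin}(x_i)}.$$

The four factors: only correct votes earn marks; samples at or below the
margin threshold $\theta \in [-1, 0]$ are treated as outliers (a sample
nearly the whole pool misclassifies is likely abnormal) and excluded — the
comparison is strict, so $\theta = -1$ retains every sample; the *bonus term*
$e^{y_i \mathrm{NF}_i}$ rewards correct votes on positive samples only, the
more strongly the more of the pool got the sample wrong, which is the
mechanism that raises sensitivity; and $e^{-\mathrm{margin}}$ is continuous
and strictly decreasing over the whole margin range, so hard (low- or
negative-margin) samples weigh more without the divergence a logarithm would
have at 0. Disabling the bonus term (`bonus = FALSE`) gives the margin-only
ablation, called **MEP** throughout; when the pruning set contains no
positive samples the two are identical by construction.

**UMEP** sums $-\ln(\mathrm{margin}(x_i))$ over the correctly classified
samples with strictly positive margin; negative-margin samples are neglected
entirely, which is precisely the behaviour MSM's exponential weighting was
designed to avoid.

**MDM** combines a margin term $f_m = -\ln(\max(|\mathrm{margin}|,
\varepsilon))$ and a diversity term $f_d = -\ln(\text{fraction of pool
correct})$ as $\alpha f_m + (1-\alpha) f_d$, summed over correctly classified
samples. As printed in the literature the margin term is undefined for
non-positive margins; we read it through the absolute value (the measure is
described as favouring low *positive or negative* margins) and clamp at
$\varepsilon = 1/M$, the smallest attainable non-zero magnitude.

**SDAcc** is a greedy forward-selection objective rather than an ordering:
per sample, a candidate classifier earns $+\mathrm{NF}^S$ when it is correct
(whether or not the current sub-ensemble $S$ is) and loses $\mathrm{NF}^S$
(sub-ensemble correct, event e01) or $\mathrm{NT}^S$ (both wrong, e00)
otherwise, where $\mathrm{NT}^S, \mathrm{NF}^S$ are the correct/incorrect
vote fractions of the *current* sub-ensemble. The textual description of the
original measure suggests different rewards for the two correct events, but
the formula as printed weights both by $\mathrm{NF}^S$; we implement it as
printed. The known weakness this produces — a wrong classifier on an 80/20
sample (e01) and one on a 20/80 sample (e00) both score $-0.2$, so samples of
very different importance are conflated — is reproduced exactly by
`sdacc_mark()` and is one of the package's reference checks. During greedy
growth the sub-ensemble can have even size; an exactly split vote counts as
incorrect (a tie is not a correct diagnosis), a convention that only affects
intermediate steps since selected sizes are odd.

## The pipeline

`run_msep()` executes the whole procedure on one split: a stratified
train/prune/test partition (default ratio 7:2:1), a pool of $M = 101$ CART
decision trees (Gini impurity, unpruned, minimum leaf 1 — `rpart` with
`cp = 0`, depth capped only by rpart's hard limit of 30) each trained on an
independent bootstrap of 30% of the training part drawn with replacement,
per-classifier marks on the pruning part, selection of the top $T = 11$
(about 10% of the pool; both odd so majority votes cannot tie), and majority
voting on the test part. `cross_validate()` repeats this over independent
random splits — a 50-repetition Monte-Carlo scheme; a literal k-fold reading
is impossible with a three-way split — and aggregates mean and standard
deviation per metric. `compare_measures()` shares one pool and one split per
repetition across measures, which is the right protocol for ablations such
as MSM versus MEP because it removes pool-to-pool variance from the
comparison.

Metrics are accuracy, sensitivity $TP/(TP+FN)$, specificity $TN/(FP+TN)$ and
the rank-based (Mann–Whitney) AUC with ties counted half, scored on the
pruned ensemble's positive-vote fraction. A metric whose denominator is
empty is reported as `NA`, never coerced to 0, and excluded from
aggregation. `rank_scores()` implements the cross-model comparison rule in
which, per metric, the best of $n$ models earns $n$ points and ties share
the mean of their slots.

## The feature extractor

`fit_autoencoder()` trains a sequence-to-sequence autoencoder built from
gated recurrent units. The encoder consumes the multichannel series one time
step at a time (each step is the vector of all channel values at that
instant); its final hidden state is the latent vector $z$ (so
`latent_dim` is the encoder width). The decoder is a GRU initialised at $z$
and fed $z$ at every step (the repeat-vector scheme), with a linear readout
back to channel space, emitting the reconstruction in forward time order.
Training minimises the mean squared reconstruction error over all
$D = \text{channels} \times \text{timesteps}$ entries,
$\mathrm{MSE} = \frac{1}{D}\sum_m (x_m - \tilde x_m)^2$, by full
backpropagation through time with Adam. Channels are standardised to zero
mean and unit variance over the training set before fitting, and
reconstructions are returned in original units.

The recurrent cell follows the standard published GRU update (update gate,
reset gate, candidate state); no claim is made about matching any particular
framework's internals, and the package's tests deliberately avoid depending
on them — correctness is guarded instead by a numerical-gradient check
(analytic BPTT gradients against central differences, relative error below
$10^{-6}$) and by convergence properties on low-rank signals. Defaults
(`latent_dim = 8`, `epochs = 30`, `learning_rate = 0.01`,
`batch_size = 16`) are configuration values chosen for the synthetic data
scale, not assertions about any external study's grid.

## What the synthetic generator emulates — and what it does not

`simulate_breath_samples()` produces the study conditions for every test in
the package, in place of clinical breath data, which is rarely shareable.
Each channel's curve is

$$r_s(t) = b + A_{c,s}\,\big(1 - e^{-t/\tau_r}\big) \quad (t \le t_{on}), \qquad
r_s(t) = b + A_{c,s}\,\big(1 - e^{-t_{on}/\tau_r}\big)\,e^{-(t-t_{on})/\tau_d} \quad (t > t_{on}),$$

the canonical chemiresistor transient: saturating rise while analyte is
present ($\tau_r$ = 15% of the window, gas-off at 60%), exponential recovery
after. The class-$c$ amplitude of sensor $s$ is
$A_{c,s} = a_s + y\,\cdot\,\text{class\_separation}\,\cdot\,\delta_s$ with fixed
gains $a_s$ spread over $[0.8, 2.0]$ and a fixed alternating-sign contrast
pattern $\delta_s = \pm 0.1\,a_s$, so the classes differ in response
*pattern*. On top of the deterministic curve: multiplicative per-sample,
per-channel amplitude jitter with coefficient of variation `amplitude_cv`
(default 0.10 — subject-to-subject variability), i.i.d. Gaussian noise
(`noise_sd`, default 0.05), and a slow random-phase sinusoidal baseline
drift (`drift_sd`, default 0.02). `positive_noise_inflation` multiplies both
noise scales for positives only, creating a ground-truth "hard positives"
regime in which a sensitivity-oriented measure should visibly out-select a
margin-only one.

The generator does **not** model real sensor chemistry: no
humidity/temperature cross-sensitivity, no analyte-specific response
spectra, no long-term drift across sessions, and time is unitless (a real
90 s window at 675 points would be 7.5 Hz, but nothing downstream uses the
rate). Consequently, passing tests demonstrate that the *selection
machinery* behaves as designed under controlled difficulty — not that any
particular clinical performance would be attained on real breath data.

`simulate_vote_matrix()` bypasses the classifiers entirely and draws
correctness indicators from a Gaussian copula: a shared per-sample
difficulty variable (weight `correlation`) induces the co-occurring errors
real pools exhibit, while each column's marginal matches its configured
accuracy exactly. This is the direct substrate for testing the measures at
scale, including exhaustive enumeration of all $\binom{15}{5} = 3003$
sub-ensembles to verify near-optimality of the greedy ordering.

## Numerical choices and degenerate inputs

* Ranking ties break by ascending classifier index under a stable sort, so
  every ranking is deterministic; greedy SDAcc seeds with the individually
  most accurate classifier, ties again to the lowest index.
* Bootstrap sizes use round-half-up of `sample_fraction * N` with a floor of
  2; a bootstrap that draws a single class is redrawn (at most 10 times)
  because a tree cannot fit one class.
* Stratified splits use largest-remainder allocation per class (fractional
  parts rounded to 9 decimals so float noise cannot decide exact ties).
  Because the per-part class counts are then deterministic, a part that
  would receive zero samples of a class is a configuration error and is
  reported immediately rather than retried.
* Natural logarithms everywhere a measure says "log"; rankings are invariant
  to the base (and to any positive rescaling of marks, also under test).
* Undefined sensitivity/specificity (empty denominators) and single-class
  AUC are `NA`, excluded from aggregation — coercing them to 0 would bias
  repeated-validation summaries.
* Problem sizes used by the shipped tests and checks were chosen to keep a
  full run comfortable on a laptop: sensor sets of 40–120 samples at 40–60
  time steps for pipeline checks, the full 13 x 675 shape for the
  dimensionality contract, vote matrices up to 10000 x 11 for marginal
  convergence, and 50-seed/50-repetition loops for the stochastic
  properties. The 7:2:1 / M = 101 / T = 11 defaults mirror the intended
  clinical protocol.

## Design choices that were genuinely open

* **Decoder conditioning.** Sequence autoencoders vary in whether the
  decoder runs forward or reversed and how $z$ enters. We condition both the
  initial state and every input on $z$ and emit forward in time: the
  simplest contract, and the reconstruction objective is direction-agnostic.
* **MSM threshold default** $\theta = -0.8$ (tunable over
  $\{-1.0, -0.9, \dots, 0\}$): retains genuinely hard samples while
  excluding near-unanimous errors, matching the outlier-elimination intent
  of the threshold term. **MDM** $\alpha = 0.5$ weighs margin and diversity
  equally.
* **UMEP gating.** Whether a classifier's UMEP mark should average over all
  samples or only those it classifies correctly is ambiguous in the
  ordering-measure literature; we gate on correctness, consistent with the
  indicator in MDM and MSM — a classifier's mark should reflect its own
  correct decisions.
* **AUC score source.** The pruned ensemble's positive-vote fraction is the
  natural ranking score for a voting classifier and is what `predict()`
  returns.

## Known limitations

* The pure-R autoencoder is intended for the package's feature-extraction
  scale (tens to hundreds of samples, tens to hundreds of time steps);
  training at the full 675-step clinical shape works but is slow, and no
  GPU path exists.
* The bonus term is defined for binary labels with 1 = positive; multi-class
  extension would require redefining which classes earn the bonus and is out
  of scope.
* Sensitivity/specificity trade off: the bonus term buys sensitivity at a
  (usually small) cost in specificity; `compare_measures()` plus
  `rank_scores()` is the intended way to check that overall standing is
  preserved on your data.
* Base learners are CARTs only; the pruning measures consume any vote
  matrix, so other learners can be plugged in at that interface, but no
  training wrapper is provided for them.
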