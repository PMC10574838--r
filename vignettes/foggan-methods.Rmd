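---
title: "Adversarial synthesis of freezing-of-gait accelerometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial synthesis of freezing-of-gait accelerometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Freezing of gait (FoG) is an episodic motor symptom of advanced Parkinson's
disease: the feet stop progressing despite the intention to walk. Wearable
accelerometers can capture it, but annotated FoG corpora are small, hard to
collect, and dominated by non-freeze samples. This package implements a data
augmentation approach: a generative adversarial network (GAN) is fitted to
nine-channel accelerometer rows (ankle, thigh and trunk sensors, each
reporting horizontal-forward, vertical and horizontal-lateral acceleration
in milli-g), and the synthetic rows it emits are then audited in two
complementary ways — statistical similarity diagnostics against held-out
real data, and a train-on-real/test-on-synthetic classifier protocol.

Rows are treated as independent tabular samples throughout. There is no
windowing, filtering or sequence modelling; that is a deliberate scope
decision, matching the tabular treatment the approach was designed around.

## Data model and preprocessing

A raw recording is a whitespace-delimited text file, one sample per line:
a millisecond time stamp, nine acceleration values, and an annotation in
{0, 1, 2} — 0 meaning "not part of the experiment", 1 "experiment, no
freeze" (standing, walking, turning), 2 "freeze". Preprocessing

1. drops annotation-0 rows (they are kept at read time so corpus-level row
   counts remain observable),
2. relabels the survivors to the binary convention **freeze = 0,
   no-freeze = 1**, and
3. drops the time and source columns, leaving an `N x 9` matrix plus a
   label vector.

The train/evaluation split is a uniform random row-level split with exactly
`floor(0.8 N)` training rows. Nothing in the source material says whether
the original split was random, chronological or subject-wise; random was
chosen because it matches the published sample-size arithmetic exactly
(912,668 of 1,140,835) and makes no subject-metadata assumptions.

Features are standardized per feature (zero mean, unit variance) with
statistics fit on the training split only. No scaler is named in the source
material; standardization is the natural partner of a generator with a
linear (unbounded) output layer. A constant feature gets its scale forced
to 1, so it maps to zero and inverts exactly.

## The adversarial model

The generator `G(z; θ_g)` maps latent noise `z ~ N(0, I_8)` to a 9-vector in
scaled feature space; the discriminator `D(x; θ_d)` maps a 9-vector to the
probability that it is real. They are trained on the two-player value
function

    min_G max_D V(D, G) = E_x[log D(x)] + E_z[log(1 − D(G(z)))]

by alternating minibatch updates: each step ascends the discriminator
objective `(1/m) Σ [log D(x_i) + log(1 − D(G(z_i)))]` on `m` real and `m`
generated samples, then updates the generator. Two generator objectives are
provided: the literal minimization of `(1/m) Σ log(1 − D(G(z_i)))` and the
non-saturating variant that instead ascends `(1/m) Σ log D(G(z_i))`. Both
share the same fixed point; the non-saturating form is the default because
its gradients do not vanish while the discriminator is still winning.

The reference architecture is fully connected throughout:

* **Generator**: 8-dimensional noise input; hidden widths 1536, 1278, 1024,
  512, 384, 256, 128, 64, 32, 16, all rectified-linear; linear 9-unit
  output. Total 4,152,071 trainable parameters, `(w_in + 1) w_out` per
  layer. The 8-dimensional input is not stated anywhere explicitly — it is
  fixed by the first layer's printed parameter count,
  13,824 = (8 + 1) × 1536. The noise distribution is likewise unstated;
  standard normal is the common default.
* **Discriminator**: the same ten hidden widths with 20% dropout after each
  dense layer, then a single logistic unit. Two divergences from the
  printed description are intentional. First, the printed layer table ends
  in a 9-unit sigmoid layer and duplicates the generator's parameter counts
  exactly (including the 8-dimensional input, inconsistent with 9
  features); a 9-unit head cannot produce the scalar probability the value
  function requires, so the table is treated as a print artifact — its
  arithmetic is still exposed via
  `foggan_architecture()$discriminator_table_widths` and checked in the
  tests, while the functional discriminator takes 9 features and ends in
  one unit. Second, the prose places dropout on the input layer and two
  hidden layers, while the table shows it after every dense layer; the
  table is the more complete specification and wins.
* **Utility classifier**: widths 64, 32, 16, 8 with 20% dropout after each,
  softmax 2-unit head; 3,402 parameters on the 9-feature input; two-class
  cross-entropy loss.

All three networks, and the backpropagation/Adam machinery behind them, are
implemented in the package on plain base-R matrix algebra; the dense-layer
engine is deliberately minimal (rectifier hidden units, linear/logistic/
softmax heads, inverted dropout) because those are the only primitives the
architecture needs.

### Training hyperparameters

| parameter | default | origin |
|---|---|---|
| epochs | 500 | published recipe |
| batch size `m` | 50 | published recipe |
| discriminator learning rate | 0.001 | published recipe |
| generator learning rate | 0.01 | published recipe |
| optimizer | Adam, β₁ = 0.5, β₂ = 0.999 | β₁ package choice (below) |
| update schedule | 1 D step, then 1 G step per minibatch | package choice |
| generator loss | non-saturating | package choice, switchable |

Only the learning rates, epochs and batch size are stated in the source
material; the optimizer itself is not named. Adam is the de-facto standard
for GANs, and its first-moment decay is set to β₁ = 0.5 rather than the
generic 0.9: high momentum amplifies the oscillation inherent in the
two-player game, and β₁ = 0.5 is the long-standing convention in the GAN
literature. With β₁ = 0.9 the reduced-width fixture configurations below
collapse visibly (the generator's rectifier units die and its output
freezes at a constant); with β₁ = 0.5 the same configurations recover both
the correlation structure and the location of test distributions.

### Conditioning by class

The 9-unit generator output leaves no room for a label channel, and nothing
states how generated samples were labeled. The package therefore trains
**one unconditional GAN per class** (`foggan()` handles this), which makes
labels exact by construction: a sample drawn from the freeze-class
generator is a freeze sample. The default class mix of generated data is
the training prevalence; any mix can be requested, which is also how the
approach supports rebalancing an imbalanced corpus. Counts follow
largest-remainder rounding so they sum exactly to the requested total.

### Fixture-scale profile

The full 4.15-million-parameter recipe targets a ~1.1-million-row corpus.
For the simulated fixtures this package tests itself on (tens of thousands
of rows), `run_config()` defaults to a scaled-down profile: generator
widths 64→32→9, discriminator 64→32→1, 30 epochs, and a generator learning
rate of 0.001. The last value deviates from the published 0.01
deliberately: on reduced networks the 10:1 generator/discriminator rate
ratio destabilizes the game (the generator overshoots the moving target and
collapses), whereas equal rates of 0.001 train stably. This is a profile
for a different problem size, not a reinterpretation of the published
recipe — the `gan_config()` defaults remain the published values.

Problem sizes used by the test suite and the acceptance script, chosen so a
full run takes minutes on a single core: 50,000-row simulated corpora for
end-to-end runs; 4,000-sample fixtures and 200 epochs for the distribution
-recovery checks; 100,000 samples for the closed-form divergence oracles.

## The simulator

`simulate_recording()` and `make_fixture_dataset()` generate seeded,
schema-faithful stand-ins for real recordings, so that every downstream
stage is testable without any data download. The signal model is three
regimes on top of per-channel gravity-projection baselines plus white
noise (SD 30 milli-g):

* **walk (annotation 1)** — a ~2 Hz sinusoid (random phase per segment and
  channel), amplitude 250 milli-g on the forward channels and 60%/30% of
  that on vertical/lateral channels: the dominant locomotion rhythm;
* **freeze (annotation 2)** — trembling in place: three random tones in the
  3–8 Hz band, with the forward amplitude *reduced* relative to walking,
  plus a fixed postural mean shift (e.g. +150 milli-g forward lean on the
  trunk): freezing changes posture and spectral content, not just
  amplitude;
* **non-experiment (annotation 0)** — baseline noise only.

These choices give the two classes separated means and spectra, so that a
small classifier genuinely separates them and the utility protocol is
meaningful at fixture scale. The simulator makes no claim of biomechanical
realism: it does not reproduce real gait spectra, harmonics, inter-subject
variability, sensor drift or annotation noise. Consequently, a passing
fixture pipeline demonstrates that the *machinery* (preprocessing, GAN
optimization, diagnostics, protocol plumbing) works end-to-end and that the
GAN can capture a learnable joint distribution — it does not certify
performance on real Daphnet-style data, whose published headline accuracies
(90.29 / 92.09 / 90.66%) depend on the real corpus and a stochastic
training run and are therefore out of desk-reproduction scope.

## Similarity diagnostics

`similarity_report()` compares a real and a synthetic feature matrix in
original units:

* **Correlation heatmaps** — Pearson correlation matrices of both sets and
  their elementwise absolute difference. Magnitudes are banded with the
  categorical scheme ≥ 0.16 "highly significant", [0.1, 0.16) "high",
  [0.01, 0.1) "moderate", < 0.01 "negligible"; the half-open boundaries
  close the gaps the published interior points leave open (0.15–0.16,
  below 0.01) without moving any stated point. A constant column gets the
  convention r = 0 off-diagonal, with a flag.
* **Cumulative sums** — per-feature running totals in row order; the only
  diagnostic that is not row-permutation invariant, by definition.
* **Log moments** — per feature, `(log10(|mean| + ε), log10(SD + ε))` with
  ε = 1e−12 guarding exact zeros. Base-10 logs were chosen (natural logs
  would be equally defensible; the source material does not say).
* **PCA** — components fitted on the standardized *real* matrix only; the
  synthetic matrix is projected into that frame. The real distribution is
  the reference, so the synthetic cloud is judged in the real coordinate
  system rather than on a frame it co-determines.
* **Distribution divergences** — per feature, the two-sample
  Kolmogorov–Smirnov statistic (exact tie handling, so identical samples
  score 0) and the Jensen–Shannon divergence with natural logs on 50
  shared equal-width bins spanning the pooled range (bounded by ln 2).

No scalar "similarity score" formula is defined in the source material; the
report's two summary scalars are `max |Δcorr|` and the mean per-feature KS
statistic — simple, bounded, zero on self-comparison, and monotone in
dissimilarity. Significance testing of these divergences, and privacy or
memorization auditing, are out of scope.

## Utility protocol

The classifier is trained on the standardized real training split only and
then scored on three evaluation sets: the held-out real rows, the generated
rows (scaled with the real training scaler), and their shuffled union.
Accuracy of the union is exactly the size-weighted mean of the parts — an
identity the tests assert — so the three numbers are one experiment, not
three. Per-class recalls on the real evaluation set are reported alongside,
because freeze is the minority class and a headline accuracy can hide a
collapsed freeze recall; the headline metric itself is left untouched, and
no class re-weighting is applied. The classifier is deliberately not tuned:
it is the measuring instrument, not the object of study.

## Numerical choices and degenerate inputs

* Logistic outputs are clamped to [1e−7, 1 − 1e−7] so the adversarial
  log-losses stay finite; cross-entropy probabilities are floored at 1e−12.
* A non-finite epoch loss aborts training with the epoch number in the
  error, rather than continuing silently.
* Weight initialization is He-normal (suited to rectifier units); biases
  start at zero.
* Minibatches are full-size only (`floor(N/m)` per epoch); the remainder
  rows rotate in across epochs through reshuffling.
* Seeds: every stochastic stage takes an explicit seed; the pipeline
  derives per-stage child seeds from one global seed, and all seeded code
  paths restore the caller's RNG state afterwards. Identical seeds give
  bit-identical training histories, parameters, samples and reports.
* Degenerate inputs fail loudly and early: empty segment plans, all-zero
  annotation corpora, single-class training sets, unfitted scalers, and
  schema mismatches all raise immediate errors naming the problem.

## Known limitations

* Rows are modelled as exchangeable; all temporal structure beyond the
  simulator's segment plans is ignored, so the synthetic data cannot be
  used for sequence-level tasks.
* Vanilla adversarial training is used by design (no Wasserstein,
  spectral-norm or conditional variants); mode collapse is possible and is
  surfaced, not prevented, by the distribution diagnostics.
* The per-class GAN decision assumes the class label is the only
  conditioning variable of interest; subject identity is not modelled.
* Published headline accuracies require the real corpus and are not
  reproduced here; the package's evidence at fixture scale is the
  utility-gap property, not the absolute numbers.
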