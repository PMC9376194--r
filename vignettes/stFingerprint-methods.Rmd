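---
title: "Methods: spatiotemporal classification and attribution fingerprinting"
author: "stFingerprint authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal classification and attribution fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Resting-state fMRI yields, for each subject, a matrix of regional time
series: `Nc` brain regions by `Nt` timepoints, with `Nt` varying across
subjects and acquisition sites. Given two groups of subjects (for
example, females and males within a clinical population), we want to

1. learn a classifier that separates the groups from the regional
   *dynamics*, robustly across heterogeneous acquisition sites and under
   heavy class imbalance;
2. explain the classifier: score every (region, time) cell of every
   subject by its contribution to the group decision — the subject's
   "fingerprint" — and reduce those scores to a reproducible group-level
   list of discriminative regions;
3. relate per-subject regional scores to clinical symptom-domain scores
   within each group.

The package implements this cycle end to end and ships a synthetic
cohort generator so that every stage is testable without access to
restricted clinical data.

# The classifier

The spatiotemporal network (stDNN) treats the `Nc` regions as input
channels of a 1D convolution over time:

* **Block 1**: temporal convolution (`F1` filters, kernel `k1`, stride
  `S1`, valid padding) followed by ReLU.
* **Block 2**: temporal convolution (`F2` filters, kernel `k2`, stride
  `S2`) followed by ReLU.
* **Temporal averaging**: the mean over the remaining time axis, one
  value per filter. This makes the representation length-invariant, so
  subjects with different `Nt` are handled natively; time points beyond
  a subject's true length (padding added for batching) are excluded
  before the convolution, which makes the forward pass exactly invariant
  to padding.
* **Site encoding**: the subject's acquisition site as a one-hot vector,
  concatenated to the averaged features. Sites never seen in training
  are encoded as the all-zero vector; this convention lets the trained
  model be applied to a fully independent cohort without retraining.
* **Output head**: one affine map to two class logits. The class-1
  probability is the softmax of the logits, which equals the sigmoid of
  the logit difference — a two-logit head and a sigmoid output are the
  same model, and the two-logit form is the one on which the margin loss
  below is defined.

## LDAM loss

With heavy class imbalance, cross-entropy training concentrates on the
majority class. The label-distribution-aware margin (LDAM) loss enforces
a per-class margin that shrinks with class size,

$$\Delta_j = C \, n_j^{-1/4},$$

rescaled by a single constant so that the largest margin equals a cap
(default 0.5), and applied inside a scaled softmax:

$$\ell(z, y) = -\log
\frac{e^{s (z_y - \Delta_y)}}{e^{s (z_y - \Delta_y)} + e^{s z_{1-y}}}.$$

The rare class must therefore be separated with a larger buffer, which
trades a little majority-class margin for minority-class generalization.
With $\Delta = 0$ and $s = 1$ the loss is exactly the two-class softmax
cross-entropy — that equivalence, and the closed-form margins, are
pinned by exact tests. Margins are a train-time device only; prediction
is the argmax of the raw logits.

Defaults: `C = 1`, cap `0.5`, logit scale `s = 30`, as in the original
formulation of the loss. Setting `ldamC = 0, logitScale = 1` recovers
plain cross-entropy training, which is how the package's own
LDAM-versus-cross-entropy comparison is run.

## Training and its regularization

Training is minibatch Adam (learning rate `1e-3`, batch 16, decoupled
weight decay `1e-4` on the weight matrices) on the mean loss, fully
deterministic given the seed. Two defaults deserve explanation because
they were chosen deliberately after studying the estimator's behaviour
on the generator's planted-signal cohorts:

* **Kernel sizes `k1 = 21`, `k2 = 9`** (receptive field 29 timepoints).
  The group signal the generator plants is an oscillation with a period
  of 10 timepoints; a receptive field spanning roughly one period is too
  short to measure band-limited power reliably, and a network so
  configured learns the training subjects by heart instead (perfect
  training accuracy, held-out minority recall near zero). A receptive
  field of about three periods lets the convolutional filters act as a
  band-power estimator that generalizes. Users working at different
  sampling rates should scale the kernels to span a few periods of the
  dynamics they expect to matter.
* **Train-time noise injection (`augmentNoiseSd = 1`)**: fresh Gaussian
  noise of one baseline standard deviation is added to every input
  presentation. With tens of minority-class subjects, a network of this
  capacity can memorize subject-specific noise; injected noise makes
  memorized features worthless while leaving the planted band-limited
  structure (which survives averaging) intact, and it keeps the training
  gradient alive after the margins are met. It is switched off with
  `augmentNoiseSd = 0`.

No batch normalization or dropout is used by default; both would add
train-time stochasticity without, in our experiments, improving held-out
minority recall.

## Normalization

Each region's time series is z-scored within subject (constant rows map
to zeros, not NaN, so degenerate inputs cannot poison the
convolutions). This removes per-site additive offsets and per-subject
scale, which is the conservative choice for multi-site data; it also
means group differences must live in the *shape* of the dynamics, not in
mean or variance. Z-scoring is a separate, explicit step
(`zscoreNormalize`) so users can substitute their own scaling.

# Evaluation design

`makeFolds` produces class-stratified folds (per-class fold sizes differ
by at most one); when every site-by-class cell has at least `k`
subjects, subjects are additionally dealt across folds within site, so
no fold is dominated by one site. `crossValidate` trains one model per
fold on the complement, derives each fold's weight-initialization seed
deterministically from the configuration seed and the fold index, and
reports accuracy, precision, recall and F1 — support-weighted across
classes, with the per-class values always attached, because a weighted
average alone can hide a collapsed minority class.

`applyModels` evaluates a list of trained models on a full external
cohort and summarizes across models. It deliberately implements both
remaining evaluations of the framework, which differ only in the cohort
passed in: *transfer* (a same-population cohort from sites the models
never saw, encoded as zero site vectors) and *specificity* (a different
population — in the synthetic setting, a cohort generated with the
planted effect removed, where a group-specific classifier should fall
back to majority-rate accuracy).

# Fingerprints and feature identification

Integrated gradients attribute the target-class logit $F$ along the
straight path from a baseline $x'$ to the input $x$:

$$IG_i = (x_i - x'_i)\,\frac{1}{m}\sum_{t=1}^{m}
\left.\frac{\partial F}{\partial x_i}\right|_{x' + \frac{t-0.5}{m}(x - x')}$$

a midpoint Riemann approximation of the path integral, computed with the
same backpropagation machinery used in training. The attributions
satisfy the completeness axiom $\sum_i IG_i \approx F(x) - F(x')$ up to
discretization error; the package's tests verify completeness within 1%
at `m = 200` on a trained network, improvement with `m`, and exactness
for linear models at any `m`. The default baseline is the all-zero
matrix — after z-scoring, the natural "no signal" reference; a custom
baseline matrix can be supplied.

Group-level feature scores are the *nested median*: per fold model, the
per-cell median of the signed fingerprints across the target-group
subjects; then the per-cell median across the fold models. Medians are
used at both levels so that a single atypical subject or one unstable
fold model cannot dominate the consensus. Maps are cropped to the
cohort-minimum `Nt` so cells align across subjects — the simplest
deterministic alignment for variable-length recordings.

The top-`p`% mask keeps the `ceiling(p/100 * Nc * Nt)` largest consensus
cells; ties at the threshold value are all kept (the achieved count can
then exceed the nominal one, and is reported). Signed scores are
thresholded — high positive attribution means evidence *for* the target
class; an absolute-value variant is a one-line change on the consensus
matrix if both tails are wanted.

# Symptom association

For each region and symptom domain, the subject's region score — the
temporal mean of their signed fingerprint row, averaged across the fold
models — is Spearman-correlated with the domain score within one group.
The p-value uses the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$, two-sided; Benjamini–Hochberg FDR
correction is applied across the full regions-by-domains family within
the group. Per-fold-model consistency (the fraction of single-model
analyses in which a row reaches `q < alpha`) is reported alongside,
since averaging before correlating and correlating before aggregating
are both defensible and the package emits both views.

A known limitation, demonstrated by the package's own simulations: when
*several* regions carry class signal, integrated gradients divide the
logit among them, so each region's score behaves like a share normalized
by the other signal regions' strengths. That dilutes region-specific
amplitude grading (the classifier needs only the pooled evidence), and
symptom-association power per region drops accordingly. The bundled
association study therefore plants the symptom-linked signal in a single
region, which isolates the mechanism under test; with five co-planted
regions, region-level association needs either larger cohorts or
attribution methods with explicit credit separation.

# The synthetic cohort generator

`generateCohort` emulates the statistical structure of a multi-site,
class-imbalanced resting-state cohort:

* baseline: stationary AR(1) noise per region (coefficient 0.3, unit
  marginal variance) — the short-memory autocorrelation of cleaned BOLD
  at typical sampling rates;
* site effects: a constant per-site, per-region offset (s.d. 0.5) and a
  site-specific recording length drawn from `ntRange` (default 100–160
  timepoints);
* group signal: in the planted regions only, class-1 subjects receive a
  sinusoid at 0.1 cycles/timepoint with random phase and a
  subject-by-region amplitude from Normal(`effectSize`,
  `effectSize`/4) — a *temporal-structure* difference that survives
  z-scoring and forces the classifier to extract dynamics rather than a
  mean shift;
* symptom: the "rrb" score is `4 a + noise` where `a` is the subject's
  amplitude in the symptom region (zero for class-0 subjects), with
  noise s.d. defaulting to `effectSize/4`; the slope 4 keeps the score
  informative about the amplitude (Spearman rho about 0.9 at default
  noise, still above 0.5 at noise `effectSize/2`). "social" and "comm"
  scores are pure noise, so domain specificity is testable;
* composition: default 80/20 subjects (the 4:1 imbalance of male-skewed
  autism cohorts) dealt round-robin across 3 sites; default 30 regions
  with 5 planted.

`generateTransferCohort` reruns the same generative law under a fresh,
deterministically derived seed with a disjoint site vocabulary — the
synthetic stand-in for an independent replication cohort.

What the generator does **not** emulate: hemodynamic response shapes,
spatial covariance between regions, realistic motion artefacts,
site-by-class confounding (sites are balanced across classes by
construction), or scanner-specific spectral colouring. Passing the
package's tests therefore shows that the estimator chain is correct and
recovers planted structure under controlled conditions — not that any
particular real cohort contains such structure.

# Reference study sizes

The test suite and the acceptance script run fixed, scaled-down studies
chosen to exercise every stage with adequate statistical power:

* classification reference study: the default 100-subject cohort, 30
  regions, fivefold CV, plus a matched transfer cohort (unseen sites)
  and a signal-free cohort for specificity and null calibration;
* imbalance study: ten seeds of a 96/12 (8:1) cohort at effect size 1.0,
  LDAM versus cross-entropy, each model evaluated on an independently
  generated same-law cohort;
* association study: twenty repetitions of a 90-subject cohort (60/30)
  with 12 regions and a single planted region, fivefold CV, 32-step
  fingerprints.

# Numerical and degenerate-case conventions

* Constant rows z-score to zeros; constant vectors in a correlation
  return NA with a `degenerate` flag rather than an error.
* Precision/recall for a never-predicted class are reported as 0.
* The percentile threshold includes all ties; the achieved cell count is
  recoverable from the mask.
* Fold, model and stage seeds are derived from one master seed by a
  fixed affine rule, so any stage can be rerun in isolation and
  reproduces its outputs bit-identically.
* Time-series files are written with 17 significant digits; a cohort
  survives a save/load round trip bit-exactly.
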