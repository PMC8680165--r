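---
title: "Modeling drug response in heterogeneous tumors with pharmacospace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling drug response in heterogeneous tumors with pharmacospace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmacospace)
```

## Overview

`pharmacospace` predicts cancer drug response for unseen samples — bulk
profiles, single cells, or cell clusters — by learning a shared latent
space from a cell-line drug screen, and then reasons about whole tumors as
mixtures of clones: kill fractions at a dosage, tumor-level IC50s, intra-
tumor transcriptomic heterogeneity (ITTH), and independent-action drug
combinations. This vignette explains the model, its assumptions, the
tunable parameters, the numerical choices, and what the synthetic-data
validation does and does not demonstrate.

## Sensitivity scores and the response panel

Drug response is carried as `s = -log2(IC50 µM)`: doubling potency adds one
unit, and larger is more sensitive. Each drug also carries its maximum
tested dosage on the same scale, `o = -log2(max dose µM)`. A pair is called
*sensitive* when its IC50 lies strictly below the maximum tested dosage
(`s > o`): an IC50 at or beyond the top tested dose can only come from
extrapolating the fitted viability curve, so such pairs are labeled
insensitive and, during training, down-weighted (below). Screens are
incomplete; a boolean mask marks observed pairs and everything downstream
ignores unobserved cells. All dosages are converted to µM at ingest so a
single unit convention holds throughout.

## Kernel features

A sample entering the model is reduced to kernel features: the Pearson
correlation of its expression fold-change vector with that of every
training cell line, computed over an essential-gene panel (a configurable
gene list; essential genes are broadly expressed, which makes the
correlations stable across platforms). Two choices matter here:

* **Fold-changes are computed against the frozen training means** stored in
  the reference basis, never against the query cohort. Prediction for a
  single cell is therefore well-defined and independent of whatever batch
  it arrives in.
* **Gene mismatches are tolerated**: correlations use the intersection of
  essential genes present on both sides (minimum 2, warning below 50%
  coverage), because scRNA-seq dropouts guarantee partial overlap.

Training data are expected on a log scale (RMA-like); single-cell TPM is
bridged with `log2(TPM + 1)` (`log_tpm()`), the conventional choice. The
transform is applied by the caller (or by `predict_from_expression()` when
it sees TPM-scale input), and remains a configuration point because no
single bridge is canonical across platforms.

## The calibrated matrix-factorization model

Predictions take the recommender form `ŝ_iu = b_i^Q + q_i · p_u` with
`p_u = x_u W_P`: drugs and samples live in a common `f`-dimensional space
and their dot product, plus a per-drug bias, is the sensitivity. A global
mean and per-sample bias are deliberately absent — they cannot be estimated
for unseen samples, so any sample-level offset must be absorbed into `p_u`.

The loss is the calibrated weighted objective

\[
\tfrac12 \Big[ \sum_{i,u} d_u\, c_{iu}\, (s_{iu} - \hat s_{iu})^2 +
\lambda (\lVert Q\rVert^2 + \lVert W_P\rVert^2) \Big] / K
\]

over the `K` observed pairs, with
`c_iu = min( f(s_iu, o_i, l), f(ŝ_iu, o_i, l) )` and
`f(s, o, l) = 1/(1 + e^{-l(s-o)})`. When both the observed and the
predicted score sit deep in the insensitive regime the pair's squared error
is suppressed (the IC50 on both sides is an extrapolation artifact); the
`min` ensures a pair is only discounted when *both* sides agree it is
insensitive, so the model cannot silence a genuinely sensitive observation
by predicting resistance.

### Training

Full-batch gradient descent at learning rate 0.01 for up to 100,000 epochs,
`f = 10` by default. Design choices that the objective itself does not fix:

* **Calibration weights are frozen within each epoch** (recomputed from the
  current predictions at the epoch start, no gradient through them).
  Differentiating through `c` would reward pushing predictions insensitive
  merely to shrink their own weights — a degenerate descent direction.
* **Regularization** is L2 on `Q` and `W_P` only, not on the biases:
  penalizing `b^Q` would distort per-drug baselines that the bias exists to
  capture. The strength λ defaults to 0.01; cross-validated recovery on
  synthetic panels is flat over at least one order of magnitude around it
  (0.001 gives indistinguishable results), so the main requirement is
  simply "small".
* **Initialization**: `W_P`, `Q` from Gaussian(0, sd 0.01); `b^Q` at each
  drug's weighted mean observed score — the closed-form optimum of the
  zero-latent model, so descent starts from a sensible baseline.
* **Early stopping** monitors the relative loss change over a 100-epoch
  window (tolerance 1e-6) but only after a 5,000-epoch burn-in: the
  bilinear factorization starts near a saddle (both factors near zero)
  where the loss is briefly flat before the latent directions break
  symmetry, and a plain plateau rule would stop there.
* **Logistic slope** `l` defaults to 1 in −log2-µM units: the weight moves
  from 0.27 to 0.73 over a ±1 unit (two-fold dose) band around the
  maximum-dosage threshold, a natural scale for IC50 uncertainty. It is
  exposed in `train_config()`.
* **Optimizer**: plain gradient descent is the default; Adam is available
  in `train_config(optimizer = "adam")` for users who want faster early
  progress, but all defaults and all validation use plain descent.

Divergence (non-finite loss) raises an error suggesting a smaller learning
rate rather than silently clipping. Identical seeds give bit-identical
parameters.

### Evaluation

Two complementary metrics, both computed per drug and pooled:
classification **accuracy** of the sensitive/insensitive call on observed
pairs, and **MAE**, the *median* absolute error of `s` over pairs whose
*observed* class is sensitive. Conditioning on the observed label keeps the
metric independent of the model under evaluation (the alternative —
conditioning on the predicted label — would let a model choose its own
evaluation set). Cross-validation holds out entire samples: the held-out
fold's expression never enters the reference basis, so kernel features of
test samples are computed exactly as they would be for genuinely new
samples.

### Indication-specific models

Two helpers reproduce the indication workflow: `indication_weights()`
builds `d_u` (default 10 for focus samples, 1 otherwise), and
`filter_drugs_by_response()` keeps drugs effective in at least 30% of the
focus cohort's observed lines — training a focused model on drugs that
never work in the indication would only add noise.

## Dose-response curves and tumor-level IC50

A predicted score becomes a two-parameter cell-death curve
`death(x) = 1/(1 + 2^{b(m - x)})` in log2-dose, with `m = -ŝ` and slope
`b = 1` by default. This is the minimal sigmoid consistent with an IC50
(death is exactly 0.5 at `x = m`) plus a slope; asymptotes are pinned at 0
and 100% cell death.

A tumor is a `mixture_curve`: clone weights summing to 1, one curve per
clone. Its aggregate IC50 is the dose at which the *mixture* kills half the
cells — the root of a strictly increasing function, found by Newton's
method started from the naive estimate `Σ w_k m_k` (the weighted
log-average, which ignores the sigmoid shape and is kept both as the
initializer and as the biased contrast). Numerical safeguards: the root is
bracketed in `[min m − 1, max m + 1]`; a Newton step that leaves the
bracket or fails to reduce the residual is replaced by one bisection step;
death fractions are clamped to `[1e-12, 1 − 1e-12]` before derivative
evaluation; and convergence is declared on the dose axis (step below
`tol = 1e-8`), not on the residual — between well-separated clones the
mixture curve is nearly flat, where a small residual does not imply a
small dose error. The naive log-space average keeps the initializer inside
the bracket and makes the whole computation shift-equivariant in log dose.
The aggregate slope is not re-estimated; when a full curve is needed the
mixture death fraction is evaluated directly.

## Heterogeneity scores

`itth_score()` is the Shannon entropy (natural log) of a cell-type or
cluster composition, after excluding components below 5% and renormalizing
the survivors. Natural log is a pure convention — any base rescales all
scores by a constant and the quartile classification is base-invariant.
Renormalizing after the exclusion keeps the score an entropy of a proper
distribution; a composition collapsing to one surviving type scores
exactly 0. `itth_tertiles()` labels samples low/medium/high by the first
and third quartiles (linear interpolation, type-7); scores exactly at a
quartile are "medium" as a deterministic tie rule. Cell-type fractions come
from an external deconvolution tool; single-cell cluster labels from an
external clustering workflow — both are inputs, not re-implementations.
Boundary conventions throughout the single-cell QC follow the strict
reading of removal rules: cells with *fewer than* 10,000 reads are removed
(exactly 10,000 is kept), a mitochondrial fraction of 25% or more removes
the cell, genes expressed (TPM > 0) in fewer than 5% of cells are removed
(exactly 5% is kept). An optional maximum-genes-per-cell cutoff exists for
suspected doublets but has no default — no general rule is defensible.

## Therapy predictions and combinations

`predict_patient_response()` operates at three granularities: per **cell**
(patient value = unweighted mean of cell kills), per **cluster** (weighted
by cell fractions), or **patient** (single pseudo-bulk profile). When every
cell sits exactly on its cluster mean the three agree; on real data the
cell and cluster levels retain heterogeneity that the pseudo-bulk erases.
Dosages are supplied in µM (log2-transformed internally); the per-drug
maximum tested dosage is the default when none is given, since that is the
largest dose with empirical support.

Combinations follow independent drug action per cluster:
`h_i + h_j − h_i h_j`, the product term being the cells killed by both
drugs. The patient-level combination is the cluster-weighted average, and
the *improvement* is the combination kill minus the better monotherapy
kill — non-negative by construction, attaining zero only when one drug
contributes nothing in every cluster. `rank_combinations()` sorts candidate
pairs by improvement (ties broken lexicographically), and
`prioritize_combinations()` applies the qualitative pre-experimental
filter: both drugs above a minimum cross-validated accuracy, and a
predicted improvement in at least one patient; both thresholds are
arguments, defaulting to 0.7 and 0 (any positive benefit).

## Pathway associations

Pathway activity is the sum of log2 fold-changes over a gene set's members
present in the matrix (coverage recorded per set; an uncovered set yields a
missing value with a warning). Drug–pathway association is the Pearson
correlation between activity and predicted cell-death fraction across
training samples, so a positive coefficient means high activity
accompanies sensitivity. No multiple-testing correction is applied by
default — the correlations are descriptive; a Benjamini–Hochberg option
exists.

## The synthetic-data generators

`generate_panel()` emits the study panel: latent sample factors
`P ~ N(0, 1)` (i.i.d.), expression `= P G + noise` through a shared random
gene loading `G`, true scores `s = b^Q + Q Pᵀ`, observed scores with
Gaussian noise and a missingness mask, and per-drug maximum dosages at the
median of each drug's true scores so both response classes are populated.
Tying expression and response to the *same* latent factors encodes the
model's core premise — kernel similarity predicts response — with known
ground truth, which is what makes parameter-recovery validation possible.
The validation conditions are 60 lines × 8 drugs × 500 genes, rank-5
truth, response noise SD 0.3 (and a noise-free contrast), 10% missing;
these sizes give stable recovery statistics while a full 5-fold
cross-validation completes in a few minutes.

Under these conditions the cross-validated recovery sits near its model-
class ceiling: kernel features are correlations, whose per-sample
normalization slightly distorts the latent geometry the scores live in, so
even noise-free panels are recovered at r ~ 0.94 and ~95% classification
accuracy rather than exactly. Replacing gradient descent with Adam, running
to the full epoch budget, or varying λ does not move this ceiling — it is a
property of correlation-kernel features, not of the optimizer.

What the generator does **not** emulate: realistic scRNA-seq count
distributions (no negative-binomial/UMI model), batch effects, doublets, or
nonlinear expression–response relationships. Passing the recovery suite
therefore shows the estimator is correct and well-conditioned under its own
assumptions — not that those assumptions hold for any particular real
dataset. `generate_heterogeneous_patient()` (clone base profiles + noise +
optional dropout) and `generate_mixture_curves()` (Dirichlet weights,
log2-IC50 uniform on [−6, 6], slopes on [0.5, 3]) play the same role for
the composition and dose-response modules.

## Serialization and the command line

A fitted model — parameters, axis labels, the frozen reference basis, the
configuration, and the loss trace — is written as a single RDS archive
(`write_model()` / `read_model()`), the R-native serialization; the round
trip is bit-exact, which the determinism checks rely on. The
`exec/pharmacospace` script exposes `train`, `predict`, `combo`, `itth` and
`simulate` subcommands as thin wrappers over the exported functions; CSV
outputs carry a header comment with a hash of the fully-resolved
configuration, flags override config-file values, and a single `--seed`
governs all randomness. Every CLI result equals the corresponding API
result by construction and by test.

## Known limitations

* The kernel is a correlation against training cell lines; queries far
  outside the training transcriptome (other tissues, other platforms) get
  features near zero and predictions collapse toward the per-drug biases.
* Slopes of predicted dose-response curves default to 1; the screen's
  per-drug slope estimates can be supplied but are not learned.
* Independent action ignores pharmacological drug–drug interactions
  (synergy or antagonism beyond clone-level complementarity).
* The entropy-based ITTH score depends on the granularity of the upstream
  clustering or deconvolution; it is comparable across samples only under
  a consistent upstream pipeline.
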