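---
title: "Gaze-weighted tensor fusion: model, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-weighted tensor fusion: model, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the model implemented by `gazecft`, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic experiments do and do not show.

## The model

The premise is that the *time course* of visual attention over an image
carries information about the emotional category the image evokes: not
only which objects a viewer fixates, but how fixation shifts while an
emotion forms. The pipeline encodes this in four stages.

### 1. Gaze-weighted multi-frame representation

A recording is a sequence of gaze samples `(x, y, onset, duration)`.
The span from the first onset to the end of the last sample is split
into `d4` equal, half-open time bins; a sample belongs to the bin that
contains its midpoint `onset + duration/2` (a midpoint exactly on a
boundary goes to the later bin; samples are never split). Per bin, each
sample votes its dwell duration into its nearest pixel; the vote image
is convolved with an isotropic Gaussian and floored at `epsilon`,
giving the fixation map `Wᵍ_f`. The gaze-and-image weight matrices are

$$W_f = d_4 \, \frac{W^{g}_f}{\sum_{f'} W^{g}_{f'}} + \mathbf{1},$$

and the representation is the 4th-order tensor with slices
`X⁴ᵗʰ[ , , c, f] = X_c ∘ W_f`. Two structural identities follow and are
enforced by tests: at every pixel `Σ_f W_f = 2 d4`, and
`(2 d4)⁻¹ Σ_f X⁴ᵗʰ[ , , , f]` equals the source image exactly. The
ratio form also makes the weights invariant to rescaling the fixation
maps, so the absolute calibration of dwell time does not matter.

Parameters:

* `d4` (default 100 for real recordings; the synthetic study uses 10):
  the temporal resolution of attention. The default matches the
  convention of indexing frames 1..100 of a normalized viewing time.
* `sigma` (pixels; default 2% of the image diagonal, roughly a foveal
  spread at typical viewing distances): width of the Gaussian applied
  to the vote image. The smoothing uses half-sample symmetric (reflect)
  padding, which conserves total vote mass exactly.
* `epsilon` (default 1e-6): positivity floor. The per-pixel
  normalization divides by the across-frame vote sum, which is zero at
  never-gazed pixels; the floor makes the weights well defined
  everywhere and the reconstruction identity global rather than
  restricted to gazed regions.
* Votes are duration-weighted by default (`weight = "count"` gives
  unit votes), since dwell time is the natural measure of attention
  allocation.
* A `skip_initial_s` option can discard the first part of each
  recording (viewers are typically re-centered before stimulus onset);
  it defaults to 0 — the centering second is part of the recorded
  span and binning it is harmless when `d4` is coarse.

### 2. Heterogeneous features and the composite feature tensor

Every frame of the representation is passed through each configured
backbone. The shipped default backbones are three deterministic
grid-mean extractors (`toy:g=2,toy:g=3,toy:g=4`): each partitions every
channel into a `g × g` grid of contiguous near-equal blocks and emits
the block means (column-major within channel), so output dimensions are
12, 27 and 48 and genuinely heterogeneous. They stand in for pretrained
CNN penultimate-layer features, keeping the package free of weight
downloads while exercising the same interfaces; an adapter can wrap any
`extract(frame) -> vector` function via `feature_extractor()`.

Because backbone dimensions differ, each backbone's frame vectors are
projected to the *smallest* backbone dimension `d1f` with a supervised
FDA projection, then stacked into the CFT of shape
`d1f × n_backbones × d4`. Choices made here:

* **FDA population**: pooled frame-level vectors from all training
  images, each frame labeled with its image's binary label. Fitting on
  time-averaged features and re-expanding was the alternative; frame
  pooling keeps within-image temporal variation in the scatter
  estimates, which is the very signal of interest.
* **Rank completion**: with binary labels the discriminant subspace of
  `(S_w + ridge I)⁻¹ S_b` has rank 1, yet `d1f` components are needed.
  The basis is the discriminant direction plus the leading principal
  components of total scatter in its orthogonal complement, then
  orthonormalized — discriminative first, variance-preserving beyond.
* **Uniformity**: the backbone already at `d1f` passes through its
  fitted projection like the others (no special-casing), so every
  backbone's block of the CFT is centered and equally processed.
* `ridge` defaults to 1e-3, enough to invert `S_w` when the pooled
  frame count is small relative to the feature dimension.
* **Backbone order** is a configuration list and is preserved into
  mode 2 of the CFT; order can matter downstream because GTDA's mode-2
  projection mixes backbones. No selection rule is imposed.

### 3. General tensor discriminant analysis

For mode `l`, with the *other* modes projected by the current
`P_k (k ≠ l)`, the between- and within-class scatters of the mode-`l`
unfoldings are accumulated, `η_l` is set to the largest eigenvalue of
`(S_l^w)⁻¹ S_l^b` (computed by Cholesky whitening to stay symmetric),
and `P_l` collects the top eigenvectors of the symmetric matrix
`S_l^b − η_l S_l^w`. Sweeps over modes repeat until the joint objective
stabilizes. Numerical choices:

* **Initialization**: the first `d*_l` columns of the identity;
  deterministic and adequate since each update is a global eigen-solve.
* **Ridge** `1e-6 · tr(S_w)/d` on `S_w` before inversion: CFT feature
  dimensions typically exceed the sample count, so `S_w` is singular.
* **Objective and monotone acceptance**: the recorded objective is
  evaluated *after* each sweep with all projections current (scatters
  and `η` recomputed), which makes it a well-defined function of the
  iterate. Because `η` is re-estimated every sweep, the value can
  wobble at numerical-noise level near the fixed point; a sweep that
  decreases the objective is rejected and iteration stops with the
  previous projections, so the reported trace is non-decreasing.
  Re-estimating `η` every sweep (rather than freezing it after the
  first) keeps the criterion consistent with the current scatters.
* **Degenerate case**: if `S_b` is identically zero the update matrix
  vanishes; the projection then falls back to the top eigenvectors of
  `−S_w`, the directions of least within-class scatter.
* **Sign convention**: each eigenvector's first non-negligible entry is
  made positive, so fits are reproducible across BLAS implementations.
* **Target dimensions**: `"auto"` keeps, per mode, the smallest rank
  retaining 95% of the eigenvalue energy of `S_b + S_w` at identity
  projections. The reduced rank must be chosen somehow; an energy
  criterion adapts to the actual spectra rather than fixing arbitrary
  integers.

### 4. L1 logistic tensor regression

The classifier is `Pr(y=1|V) = σ(⟨Z, V⟩ + b)` with `Z` shaped like the
transformed CFT. The likelihood is the standard Bernoulli one in
`σ(⟨Z, V⟩)`; note the objective is concave in `Z` only through the
sigmoid — a log-likelihood written directly on the inner product would
be undefined for non-positive logits, so the sigmoid form is the one
implemented. Fitting minimizes the negative log-likelihood plus
`λ‖Z‖₁` by FISTA: soft-thresholding prox, backtracking line search
(doubling the local Lipschitz estimate until the majorization holds),
and an adaptive restart that falls back to a plain proximal step
whenever the accelerated candidate would increase the objective — so
the recorded objective history is non-increasing.

* **Intercept**: fitted by default, as an appended constant column
  excluded from the prox (unpenalized). The transformed CFT features
  are not centered, and a boundary forced through the origin measurably
  caps held-out accuracy on otherwise separable data; `intercept =
  FALSE` restores the homogeneous model.
* `λ = "auto"` selects from the grid `10^seq(-3, 1, length.out = 9)` by
  3-fold stratified cross-validated F1; ties resolve to the first
  maximizer, and the folds are seeded for reproducibility.
* `max_iter = 500`, `tol = 1e-7` (relative objective change); ties at
  probability exactly 0.5 classify as 0, deterministically.

## The synthetic study

The generator emulates the study setting end to end, at a scale chosen
so the full pipeline and its tests run in about a minute on one CPU:
200 images of 32×32 px, `d4 = 10`, three grid-mean backbones
(g = 2, 3, 4), one pooled subject, one binary category, a seeded 75/25
train/test split.

* **Scenes**: a noisy gray background (sd 0.05) plus 2–3 soft radial
  blobs ("objects") with random radii (3–6 px) and random per-channel
  intensities. The two objects that serve as scanpath attractors sit at
  canonical positions — fractions (0.3, 0.3) and (0.7, 0.7) of the
  image, with small jitter (sd 4% of the side) — emulating a controlled
  fixed-layout stimulus; any third blob is placed uniformly at random.
  The anchoring matters: every stage of the classifier is linear in the
  grid-mean features, so a class signature that lands at a different
  image location per draw would cancel in expectation and no linear
  method could detect it. Anchoring is what makes the planted class
  difference the kind of signal the method is designed for.
* **Scanpaths**: a two-attractor dwell/jitter process sampled at 60 Hz
  for 2 s with 2 px Gaussian jitter. Class 0 dwells on the first object
  throughout; class 1 dwells on the first object and shifts to the
  second halfway through viewing. This is the simplest dynamics that
  expresses a class-dependent *change* of attention over time; richer
  saliency-driven scanpath models are deliberately out of scope.
* **Planted tensors** (`gen_planted_cft`) test GTDA and LTR in
  isolation: a mode-1 mean shift `effect · (u ∘ e₁ ∘ e₁)` with known
  `u`, or labels drawn from `σ(⟨Z, V⟩ / noise_sd)` with a known sparse
  `Z` (zero temperature makes labels the sign of the logit).

What passing shows — and does not. On this data the pipeline reaches
held-out F1 near 1 while a label-permuted control stays at chance. That
validates the machinery: the representation preserves and time-indexes
attention, the fused tensor carries the temporal signature, and
GTDA+LTR extract it. It does *not* predict performance on real gaze
data, where attention dynamics are noisier, objects are not spatially
aligned across images, labels are subjective, and features come from
deep backbones.
One artifact worth knowing: under permuted labels the cross-validated
fit often degenerates to an intercept-only majority rule, whose F1 is
`2p/(1+p)` (≈ 0.67 at prevalence 0.5) rather than `p`; the permuted
control can therefore sit somewhat above prevalence without indicating
signal.

## Degenerate inputs and conventions

* Indices are 0-based in all file formats (`x` = column, `y` = row,
  origin top-left) and 1-based inside R; the conversion happens at the
  I/O boundary.
* Mode-`l` unfolding orders the remaining modes ascending, the
  lower-numbered one varying fastest — consistent with R's column-major
  layout for mode 1; `mode_product` satisfies
  `unfold(T ×_l U, l) = Uᵀ unfold(T, l)`.
* Empty recordings, single-class label vectors, non-positive `sigma` or
  `epsilon`, shape mismatches, and an empty test split are errors, not
  silent defaults. Degenerate precision/recall counts use the
  0/0 → 0 convention. Welch's test refuses samples of size < 2 or zero
  variance; p-values are two-sided.
* Fitted artifacts are persisted with base R serialization together
  with an MD5 hash of the producing configuration; loading with a
  mismatched hash is an error.

## Known limitations

* Binary, per-category classification only; multi-label structure is
  handled as independent one-vs-rest models, and multi-class GTDA is
  not implemented.
* The coefficient tensor `Z` is unstructured; low-rank (CP/Tucker)
  regularization is out of scope.
* No fixation/saccade event detection or blink filtering: gaze samples
  are taken as given.
* The default extractors are deterministic stand-ins; conclusions about
  deep-feature behavior require wiring real backbones through the
  adapter interface.
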