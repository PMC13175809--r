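---
title: "TriViewMIL: models, protocol, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TriViewMIL: models, protocol, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(TriViewMIL)
```

This vignette is the package's own account of what it computes and why it
is built the way it is: the multiple-instance model and its assumptions,
the preprocessing and training protocol, the conventions behind every
metric, the synthetic data the test suite relies on, and the choices made
where the design was genuinely open. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The task and its assumptions

A knee MRI study carries labels at the exam level — abnormality, ACL tear,
meniscal tear — while the input is three ordered slice stacks (sagittal,
coronal, axial). Two assumptions shape the model family:

* **Instance sparsity.** Evidence for a finding occupies a small,
  contiguous subset of slices; an aggregator should be able to concentrate
  on those slices rather than dilute them into a global average.
* **View complementarity.** Different findings are conspicuous in
  different planes, so the three views carry non-interchangeable
  information and the fusion step should treat them asymmetrically.

Both assumptions are testable against the aggregation baselines the package
ships (mean, max, gated-attention MIL pooling) under the identical
encoder, fusion head and training protocol.

## Preprocessing

Cleaning operates at the study level: exact duplicates are removed by
hashing the study identifier together with its ordered view contents, and a
study is accepted only if all three views are present, decodable as rank-3
arrays with positive spatial dimensions, and entirely finite. Rejection is
a value carrying the complete list of failed checks, written to a JSON-lines
manifest.

Standardization then proceeds per study:

1. **Slice sampling.** A fixed count `S` of slices is taken per view with
   the uniform index rule: output slice `k` (0-based) is input slice
   `floor(k * n / S)`. The rule is monotone, reduces to the identity at
   `n = S`, strides when `n > S`, and repeats slices when `n < S` — one
   formula covering both regimes with no padding artifacts.
2. **Resize and crop.** Every slice is bilinearly resized and
   center-cropped to `R x R`. Resizing is implemented as two explicit
   interpolation-weight matrix products under the half-pixel-center
   convention, so its behavior is pinned exactly: resizing to the same size
   is the identity, constants are preserved, and a `2R` checkerboard
   downsized to `R` averages each 2x2 block.
3. **Intensity normalization.** Intensities are min-max scaled to [0, 1]
   over the whole study (the "fixed range" convention adopted here), then
   z-scored with a single mean and a single *population* standard deviation
   over all pixels of all three views. The divisor is floored at `1e-8`;
   a constant study maps to all zeros and is flagged degenerate rather than
   producing NaNs.
4. **Augmentation** (training only): one rotation angle, uniform within
   ±10° by default, and one horizontal-flip decision with probability 0.5
   are drawn per view and applied identically to every slice of that view,
   preserving within-view anatomical coherence. Both knobs are
   config-exposed.

The pipeline output is always a `(3, S, R, R)` tensor per accepted study,
regardless of input slice counts, and the whole pipeline is deterministic
given input bytes, configuration, and seed.

## The model family

**Encoder.** The default desk-scale slice encoder is a four-block strided
convolutional network (1 → 16 → 32 → 64 → D channels, 3x3 kernels, stride
2, ReLU, global average pooling). The encoder is a contract, not a fixed
component: any function mapping one `R x R` slice to a `D`-vector can stand
behind `encodeSlices()`, including a heavyweight pretrained backbone at
`D = 2048`; nothing in the package requires one.

**Multi-scale attention aggregation.** Within a view, slice embeddings are
average-pooled along the slice axis at each configured odd kernel (stride
1). Window truncation at the stack boundary — averaging over valid entries
only — avoids the edge bias that zero padding would introduce. Each scale
has its own `D → E` projection and learned scale embedding; a learned
positional embedding over slice index (shared across scales) is added by
default, because slice order is anatomically meaningful; it can be switched
off, which makes the aggregator exactly permutation-symmetric (a property
the tests exploit). The per-scale token sets are concatenated — attention
can then mix information across scales — and processed by pre-norm
multi-head self-attention blocks (feed-forward width `2E`, ReLU; unstated
internals follow standard practice). A single learned query scores the
transformed tokens; the softmax readout weights are exposed per exam, view
and token, which is what makes the aggregation inspectable.

Pooling-then-projection (rather than projecting before pooling) was chosen
because the two orders have the same expressive power at these widths and
pooling first is cheaper.

**Fusion.** The three view embeddings, in fixed anatomical order, are
concatenated and classified by `linear(mlp_hidden) → ReLU → dropout →
linear(3)`; a view-averaging variant replaces concatenation for the
ablation study. Outputs are plain logistic probabilities — no temperature
scaling — so calibration metrics measure the model as trained.

**Baselines.** Mean and max pooling apply the same `D → E` projection as
the main path's kernel-1 scale; gated-attention MIL pooling scores each
slice by `w'(tanh(V'h) ⊙ σ(U'h))` with softmax normalization. With kernels
`{1}` and the attention pathway zeroed, the multi-scale aggregator reduces
*exactly* to mean pooling — the test suite asserts this equivalence to
1e-5, which pins down the ablation semantics.

**Key parameters** (benchmark values in parentheses): encoder output `D`
(2048), embedding `E` (256, divisible by the 4 heads), attention layers
(2), pooling kernels ({1, 3, 5}, odd so windows center on a slice), fusion
hidden width (512), dropout (0.2), slices per view `S` (32), resolution `R`
(224). The scaled-down configuration used throughout the tests and the
acceptance script — `D = E = 32`, one attention layer, `S = 8`, `R = 32`,
200 training exams — was chosen as the smallest setting at which the
planted-signal learning dynamics are still clearly visible on a single CPU;
its optimizer settings (batch 8, peak learning rate 5e-3, one warmup epoch,
five epochs) are correspondingly rescaled from the benchmark protocol
(batch 16, peak 1e-4, five warmup epochs, fifty epochs).

## Automatic differentiation

No deep-learning framework is involved: gradients come from a small
tape-based reverse-mode engine inside the package (matrix multiply, bias
broadcast, activations, row softmax, layer norm, attention building blocks,
im2col convolution, global average pooling, dropout, BCE-with-logits).
Every operator's gradient is verified against central finite differences in
the test suite, and a full-model spot check compares end-to-end gradients
numerically (agreement there is bounded by ReLU kinks inside the
finite-difference interval, so that check uses a relative 2% tolerance while
the per-operator checks pass at ~1e-9). Convolution uses cached gather
indices and a sort/cumsum scatter for its input gradient, which is what
makes CPU training of the tiny configuration practical.

## Training and evaluation protocol

AdamW (betas 0.9/0.999, eps 1e-8 — framework-conventional defaults,
recorded in the run manifest) with weight decay applied to all parameters.
The learning rate is scheduled per optimization step: a linear ramp from 0
to the peak over the warmup steps (warmup starting at zero; only the
endpoints were fixed a priori), then cosine annealing that lands exactly on
the floor at the final step. Validation macro AUROC is computed after every
epoch; the selected checkpoint is the earliest epoch attaining the maximum
(reproducibility over recency), with no early stopping. The test split is
touched exactly once, after training ends; exam-id overlap between splits
aborts the run before any optimization.

The multi-seed protocol trains every method once per seed on identical
splits and identical preprocessing, reports mean ± *sample* standard
deviation (the multi-run reporting convention; note the normalization step
uses the population convention — the two conventions serve different
purposes and are deliberately not unified), and compares methods to a
designated reference with seed-paired two-sided t tests. Zero-variance
difference vectors are flagged degenerate instead of producing unstable t
statistics: all-zero differences give `t = 0, p = 1`; constant nonzero
differences give `p = 0`. Differences equal up to floating-point
representation count as zero-variance.

**Metric conventions.** AUROC uses midranks (ties count one half); average
precision processes tied scores as one threshold group; F1 uses the fixed
0.5 threshold with the 0/0 → 0 convention; Brier is the plain mean squared
error. All four are verified against brute-force oracles (exhaustive
pairwise comparison; threshold enumeration; direct means) to 1e-12 on
hundreds of tie-heavy random instances. Macro values are unweighted means
over exactly the three labels.

**Robustness perturbations.** Two test-time perturbations are provided:
a constant intensity shift (default +0.5 post-normalization units) and view
dropout (exactly one uniformly chosen view zeroed, seeded). The magnitudes
are conventions of this package — config-exposed defaults — since only the
perturbation *types* are externally fixed; the tests assert only the
directional property that view dropout degrades median macro AUROC.

## Synthetic data: what it does and does not establish

The generator emulates the public three-view benchmark *layout* and a
learnable signal, not MRI physics. Each exam has three views with variable
slice counts, Gaussian background (mid-gray 0.5, sd 0.1), float32 NPY
storage (arrays are quantized to float32 at generation so files round-trip
bit-for-bit), and per-label CSVs. Labels: ACL and meniscus tears are
independent Bernoulli draws (defaults 0.20 and 0.35); a no-tear exam is
abnormal with probability 0.50, giving an overall abnormality rate near
0.74 — a label mix resembling the public benchmark's. Positives receive a
bright ellipsoid (default contrast 3 background standard deviations,
centered uniformly in the central region, spanning a contiguous slice band)
planted in a label-specific view subset: ACL in sagittal + coronal,
meniscus in coronal + axial, extra abnormality in one random view. The
hierarchy *tear implies abnormal* holds by construction, and the view
pattern makes the three labels separable only by using view identity —
which is exactly what learned fusion must exploit to beat view-agnostic
pooling. One seeded substream per exam, derived by counter, makes each
exam's content independent of how many exams are generated.

Passing tests on these data establish that the pipeline is mechanically
correct and that the model can extract a planted, view-structured,
intensity-coded signal. They do not establish clinical performance:
real MRI texture, scanner variation, lesion morphology, label noise, and
class-conditional slice statistics are all absent, so no number produced
on synthetic data should be read as an estimate of benchmark or clinical
accuracy.

## The planning optimizer

The performance-planning module minimizes `J(u) = -P(u) + beta * R(u)` over
an action vector under box and per-step smoothness constraints, by
projected gradient descent with gradients from user-supplied closed forms
or central finite differences. Projections are composed box-first, then
smoothness; for a box intersected with a step ball this composition is not
an exact projection onto the intersection in general, which is why the
bundled benchmark problems keep one constraint active at a time and the
composition order is documented here. The step size is fixed, with opt-in
halving on objective increase. Squared-hinge penalties
(`sum(max(0, c_i)^2)`), torque-limit violations, bilateral force symmetry,
and the weighted total loss are provided as building blocks. This module —
like the multimodal fusion, focal-style loss, and recurrent-state units —
is a **conceptual extension**: fully specified, unit-tested against
analytic optima, and absent from the benchmarked visual-only classifier
(`activeExtensions()` audits a configuration for exactly this). The
focal-style loss is implemented with its asymmetric modulators exactly as
formulated, including the nonstandard negative-class modulator; whether
that form is intended is not adjudicated here, and `gamma = 0` reduces it
to plain BCE, which the tests pin to 1e-9.

## Numerical conventions in one place

* Probability clamp for log losses: `1e-7`; z-score sd floor: `1e-8`.
* Layer-norm epsilon: `1e-5`; attention scaling `1/sqrt(E/heads)`.
* Degenerate t-test rules as above; sample sd everywhere in reporting.
* Checkpoint tie-break: earliest best validation epoch.
* Alignment loss sums over *ordered* modality pairs (each unordered pair
  twice), reading the summation literally; features are unit-L2 normalized
  first, so the loss is scale-invariant and zero exactly at directional
  agreement.
* The latent risk activation is tanh by default (sigmoid switchable).
* Subgradient convention at the hinge boundary of constraint penalties: 0.

## Known limitations

Single-CPU training only; no pretrained encoders are bundled; the synthetic
generator does not model MRI physics; the PGD projection composition is
inexact for simultaneously active box and smoothness constraints; no
multiple-testing correction is applied across the paired tests (matching
the protocol it implements); and parameter/FLOP accounting for large
encoders is out of scope.
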