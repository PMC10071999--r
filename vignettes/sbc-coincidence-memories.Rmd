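---
title: "Sparse binary coincidence memories: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse binary coincidence memories: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbcmem)
```

This vignette explains the model the package implements, what every
tunable parameter means and why its default was chosen, what the
synthetic data generator does and does not emulate, and the numerical
and design decisions that were genuinely open.

## The model

The classifier consumes 8-bit greyscale rasters (e.g. 28×28). Pixels are
centred by subtracting 127, giving bipolar inputs in [-127, 128].

**Feature detection.** An address-decoder element (ADE) of width *n*
subsamples *n* distinct pixels (no multapses) and computes the signed
sum `activation = sum_i input_i * weight_i`. It fires when the
activation reaches its threshold (inclusive inequality). Elements are
organised in address decoders (ADs) of *w* elements sharing one width;
different decoders use different widths so they detect features of
different sizes. Two weight types are supported — binary (-1/+1, with a
per-synapse longevity used by structural plasticity) and int8 (uniform
on [-127, -1] ∪ [1, 127]) — and two input modes: `greyscale` (default;
the centred value multiplies the weight) and `binary` (the centred value
is binarised to its sign, 0 → -1; the event-based variant that discards
greyscale information at a small accuracy cost).

**Synapse placement.** Pixels are drawn from the square root of the
global pixel-mass distribution of the training images. The square root
flattens a Poisson-like count vector toward homoscedasticity and lets
synapses land slightly outside the densest ink. Draws come from a
random-walk Metropolis chain on the pixel grid (proposal: uniform over
the 7×7 offset box excluding the origin, re-proposing at borders). The
re-proposal makes the proposal density 1/n_valid(x), which differs near
borders, so the acceptance ratio carries the Hastings correction
`min(1, T(y) n_valid(x) / (T(x) n_valid(y)))`; the stationary law is
then exactly `T / sum(T)`, which the test suite verifies by a
chi-squared fit. The chain starts at the argmax pixel and discards
1,000 burn-in steps. Locality: each element's pixels must lie within a
Chebyshev box of radius *r* around a centroid drawn from the same chain
(widths 6/8/10/12 map to radii 2/3/3/4); draws violating locality or
uniqueness are rejected, with a deterministic failure after
`max_rejects` (10,000) rejections rather than a silent livelock.

**Unsupervised phase.** Images are presented in random order with
replacement (default: twice the training-set size, so small sets can
still fill adaptation intervals). Firing events are accumulated over
intervals of `interval_t` presentations (default 2,000) and compared
with `target_rate * interval_t` (default 1%, i.e. 20 events). Within a
±25% dead band nothing moves; outside it the threshold is re-set to the
**achievable cut closest to the target count**, computed from the
interval's empirical activation distribution. A plain k-th order
statistic is not used because integer activations carry large atoms —
most prominently the exact constant an element sees whenever its whole
pixel cluster is background — and a quantile landing on such an atom
produces 50–80% firing instead of 1%. On a constant input stream the
closest-cut rule reduces to the classic ±1 oscillation around the single
achievable activation value. The first full interval serves purely as
calibration (thresholds start at 0 and are set from the first interval's
activations); `step = 0` disables all threshold movement.

Alongside, Hebbian structural plasticity runs per firing event: the
smallest signed contributor to the crossing sum loses one longevity
point (floor 0), the largest gains one (cap 255); ties go to the lowest
synapse position, and a degenerate argmin == argmax leaves the element
unchanged. At interval boundaries, synapses with longevity below
`critical` (default 1, with default longevity 16) are replaced by fresh
draws around the element's original centroid and their weight redrawn.
Two timing rules matter and were set after direct measurement:
plasticity is suspended during the calibration interval (before a
threshold exists, "firing" does not identify a feature, and mass
replacement at the calibration boundary destabilised the rates), and no
replacement happens at the final boundary (a fresh synapse shifts the
element's activation scale and needs at least one further interval of
threshold re-tracking). With these rules the held-out mean firing rate
lands at ~1% in every regime the tests exercise. Labels are never read
in this phase.

**Supervised phase.** One pass through the training set in dataset
order. For every example, every coincidence between firing elements of
the row and column decoder of each memory sets the example's class bit
(one-hot depth). Half-size memories pair a decoder with itself and store
only the strict upper triangle j < k — the diagonal is a
self-coincidence carrying no pairwise information. Because writes are
ORs, the final bit state is independent of training order and repeated
passes are no-ops; both properties are asserted bit-exactly in the
tests.

**Inference.** The firing patterns are computed once per image, the
probed locations are identical to the ones writing would touch, and the
per-class counts of set bits are summed across memories. The largest sum
wins; ties break to the lowest class index; an all-zero count vector is
flagged `no_evidence` and reported as class 0.

## The kernel view

Unrolling all coincidence locations into one long binary vector **b**
(length `m = sum` over memories of addressable locations;
`coincidence_space_size()` computes it analytically, e.g.
`3 * 2048^2 = 12,582,912` for three full memories over w = 2,048), the
logical AND of two unrolled vectors is a dot product, so the overlap
|a ∩ b| is a valid Mercer kernel. `lsc_fit()` solves
`(K + ridge I) H = Y` for one-hot targets and `lsc_predict()` takes
`k* · h_i` as the class indicators. The ridge (default
`1e-6 * trace(K)/n`) exists because near-singular Gram matrices occur
whenever two training cases activate nearly identical bit sets; exact
inversion is numerically unsafe, and the default is small enough to
leave well-conditioned solutions unchanged to the tested tolerances.
Bit vectors are stored as sorted index sets: at 1% firing the expected
density is ~10^-4, so sparse sets beat any dense representation.

## Parameters at a glance

| parameter | default | units | why |
|---|---|---|---|
| `w` | 2,048 (presets); 512 in desk-scale examples | elements | memory size grows as w²; 1% of w must still give a few active elements per decoder, so small experiments use w ≥ 256 |
| `n` (per decoder) | 6/8/10/12 or 6/10/12 | synapses | different widths detect features of different spatial scales |
| `locality_radius` | 2/3/3/4 by width (`round(n/3)` clamped to [2,4]) | pixels | interpolates the printed width→radius pairing; radius 3 for width 8 |
| `target_rate` | 0.01 | probability | sparse patterns keep coincidences informative and memories sparse |
| `interval_t` | 2,000 | presentations | 20 expected events per interval make the count statistically meaningful; far smaller intervals make the 1% quantile unreliable |
| `step` | 1 | activation units | gates adaptation; movement itself is quantile-based (see above) |
| longevity default / cap / critical | 16 / 255 / 1 | events | a persistently losing synapse is replaced after ~16 losing firings |
| `max_rejects` | 10,000 | draws | deterministic sampling-exhausted failure |
| ridge | `1e-6 * trace(K)/n` | kernel units | regularises near-singular least-squares solves |

## The synthetic generator

`make_prototypes()` draws, per class, a fixed set of filled discs with
hard edges (overlap takes the max intensity); centres are uniform on the
central `(rows-8) × (cols-8)` window, so ink mass is centre-biased and a
quarter or more of all pixels carry exactly zero mass — the structure
that justifies mass-guided synapse sampling. `make_dataset()` renders
each image with an integer translation uniform on `[-jitter_px, +jitter_px]²`
(default 1) and Gaussian intensity noise (SD 8) on the stroke pixels
only; the background stays exactly 0, as in scanned-handwriting rasters.
Class imbalance is expressed by exact per-class counts.

What this emulates well: centre-biased global ink mass, class-specific
local features, per-image intensity variability, exact-zero borders.
What it does not: stroke curvature and elastic deformation, inter-writer
style variation, aliasing between similar character classes, and the
scale of real benchmarks (tens of images per class, not thousands).
Passing tests therefore demonstrate the mechanism — sparsity control,
memorisation, robustness trends, kernel equivalence — not benchmark
accuracy on handwriting; the full-size runner in
`inst/scripts/mnist_benchmark.R` exists for that.

## Numerical choices and degenerate inputs

* Activations, thresholds and counts are integers throughout; firing is
  `>=`, so an activation exactly at threshold fires.
* Noisy pixels are rounded to the nearest integer with ties away from
  zero (base `round()` is banker's rounding), then clamped to [0, 255].
* Per-image frozen noise streams are keyed by `(spec seed, image index)`
  so subsetting a dataset never reshuffles realisations.
* Prediction ties break to the lowest class index, deterministically; an
  all-zero count vector is a flagged degenerate, not an error.
* All-zero sampling targets, empty training sets, empty test sets,
  out-of-range labels and mismatched image shapes raise immediate,
  specific errors.
* Every stochastic entry point takes an explicit seed and restores the
  caller's RNG state; a configuration seed determines the entire
  training trajectory bit-exactly (asserted in the tests).

## Very small training sets

With an n-per-class subsample far below `interval_t`, no adaptation
interval completes: thresholds stay at their initial value of 0 and
roughly half of all elements fire per image. The classifier then
operates as a dense pattern-overlap matcher — exactly memorising the few
training examples — which is the behaviour that makes one-shot learning
work (0.76–0.85 accuracy at one example per class on the 10-class
synthetic task, against 0.1 chance). Forcing sparse calibration from a
handful of presentations was measured far worse (~0.35); the package
therefore leaves the default `interval_t` alone in the single-shot path.

## Problem sizes used by the tests and acceptance script

The test suite runs the full pipeline at w = 96–512 on synthetic sets of
120–3,000 images, and the homeostasis and robustness checks use a
2,000-image, 10-class set with decoders of w = 512 and the 1%/2,000
adaptation defaults; the acceptance script reproduces the homeostasis
measurement at exactly that scale. These sizes were chosen so every
stage runs at full fidelity (no stubbed phases) while a complete check
finishes in minutes on one CPU.

## Known limitations

* Memories are dense logical arrays; the compressed single-class-bit
  storage variant and the two-half-memories-in-one-allocation packing
  are not implemented.
* Synaptic delays (spatio-temporal coincidences), N-of-M class
  encodings, probabilistic writes, data augmentation and layered
  memories are out of scope.
* The forgetting mechanism (`random_forget()`) is exposed with no
  cadence policy; when and how many bits to forget is problem-specific.
* The Gram matrix is built by pairwise sparse intersections — fine for
  the hundreds of training cases the kernel diagnostics target, not for
  60,000.
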