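# sbcmem — sparse binary coincidence memory classifiers

`sbcmem` implements a biologically-inspired classifier for greyscale
raster data (MNIST-shaped images) built from two pieces:

* **Address decoders (ADs)** — vectors of *w* feature detectors
  ("address-decoder elements", ADEs). Element *j* subsamples *n* pixels
  of the input and computes

  ```
  activation_j = sum_i input_i * weight_i        (over the element's synapses)
  element j fires  iff  activation_j >= theta_j
  ```

  The synapse pixels are drawn by Metropolis–Hastings sampling from the
  square root of the global per-pixel "ink mass" of the training images
  (so informative pixels are sampled often and blank corners essentially
  never), under a spatial locality constraint and with multapses
  (duplicate pixels within an element) disallowed. The thresholds
  `theta_j` are learned unsupervised by homeostasis: each element is
  driven toward a target firing probability (default 1%), while Hebbian
  structural plasticity replaces persistently under-contributing
  synapses. No labels and no gradients are involved.

* **Sparse binary coincidence (SBC) memories** — 2D bit stores indexed
  by pairs of firing elements from two decoders, with one bit per class
  at every location. Supervised learning is a **single pass**: for each
  training example every coincidence `(j, k)` between firing elements
  sets the example's class bit,

  ```
  for all j, k :  j fires in AD1 and k fires in AD2  =>  set SBC[j, k, class]
  ```

  Writes are idempotent ORs, so training order is irrelevant and a second
  pass changes nothing. Inference reads the same locations and sums the
  set bits per class across all memories; the largest sum is the
  predicted class. The mechanism is non-parametric, robust to input
  noise, and supports one-shot and continuous learning (bits added later
  can be balanced by `random_forget()`).

The package also implements the kernel view of the same mechanism: the
coincidence pattern of an input, unrolled into one long sparse binary
vector **b**, turns the logical AND of two such vectors into a dot
product — a valid set-intersection (Mercer) kernel. `gram_matrix()`,
`lsc_fit()` and `lsc_predict()` provide least-squares classification
(`h_i = K^-1 y_i`, `indicator_i = k* . h_i`) on that kernel, and
`class_subset_report()` exposes the class-subset cardinalities and
intersections that explain what the memories store.

A built-in generator (`synth_image_set()`) produces labelled 28×28
images with the statistical structure the method assumes (centre-biased
ink, class-specific local features, optional class imbalance), so the
whole pipeline is testable without downloading anything. IDX
(MNIST-dialect) files are read and written by `read_idx()` /
`write_idx()`; the two noise models of the robustness experiments
(clamped Gaussian, salt-and-pepper) are applied with frozen ("static")
per-image realisations by `freeze_noise()`.

## Worked example

```r
library(sbcmem)

train <- synth_image_set(n_classes = 10, n_per_class = 200, seed = 1, dataset_seed = 101)
test  <- synth_image_set(n_classes = 10, n_per_class = 50,  seed = 1, dataset_seed = 202)

fit <- sbc_classifier(train, preset_three_ad(w = 512, seed = 1))
fit
#> Sparse binary coincidence memory classifier
#>   decoders: 3 (widths n = 6, 10, 12; w = 512, 512, 512; binary synapses)
#>   memories: 3 (3 full, 0 half); classes: 10
#>   occupancy: 36,945 bits set of 7,864,320 (0.47%)

evaluate(fit, test)$accuracy
#> [1] 0.972

mean(sapply(fit$ads, function(a) mean(decoder_firing_rates(a, test))))
#> [1] 0.0099      # homeostasis holds the ~1% target on held-out data

v <- unroll_bit_vector(fit, test$images[, , 1])
c(card = length(v), m = attr(v, "m"))
#> card      m
#>   26 786432    # ~26 active coincidence bits in a 786,432-bit space
```

Reading the output: the three decoders fire ~1% of their 512 elements
per image, so each image activates a few dozen coincidence locations out
of `3 * 512^2 = 786,432`; after one supervised pass only 0.47% of all
class bits are set, yet bit-count inference scores 97% on held-out
images. `preset_four_ad()` gives the heavier benchmark layout (widths
6/8/10/12, six full + four half-size memories); `noise_sweep()` and
`single_shot_curve()` reproduce the robustness and one-shot experiments
on any labelled set.

A thin command-line front end ships in `inst/cli/sbcmem`
(`synth | train | infer | evaluate | sweep-noise | single-shot`), and
`inst/scripts/mnist_benchmark.R` runs the full-size benchmark on
user-supplied MNIST/EMNIST IDX files.

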