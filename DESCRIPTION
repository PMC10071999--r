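Package: sbcmem
Title: Sparse Binary Coincidence Memory Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-pass supervised classification with sparse binary
    coincidence (SBC) memories. Address decoders of sparse binary feature
    detectors are learned unsupervised by homeostatic threshold adaptation
    and Hebbian structural plasticity from the square-root-transformed
    global pixel-mass distribution of the training images (sampled by
    Metropolis-Hastings). Coincidences between firing detectors index 2D
    bit memories holding one bit per class, written in a single supervised
    pass and read back at inference by bit counting. Includes IDX
    (MNIST-dialect) input/output, Gaussian and salt-and-pepper noise
    models with frozen (static) semantics, noise-robustness sweeps,
    single-shot learning curves, a synthetic labelled-image generator, and
    the equivalent set-intersection (overlap) kernel formulation with
    least-squares classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
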