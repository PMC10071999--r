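# Shared fixtures, built in code at test time.

# A small uniform sampling target over an nr x nc grid.
uniform_target <- function(nr, nc, value = 1) {
  structure(list(relative_mass = rep(value, nr * nc), image_shape = c(nr, nc)),
            class = "sampling_target")
}

# A sampling target with arbitrary relative masses.
target_from_mass <- function(relative_mass, shape) {
  structure(list(relative_mass = as.double(relative_mass), image_shape = shape),
            class = "sampling_target")
}

# A hand-built single element for plasticity tests.
manual_ade <- function(pixels, weights, threshold = -1000L,
                       synapse_type = "int8", longevity = NULL,
                       input_mode = "greyscale") {
  if (is.null(longevity)) longevity <- rep(16L, length(pixels))
  structure(list(pixels = as.integer(pixels), weights = as.integer(weights),
                 longevity = as.integer(longevity),
                 threshold = as.integer(threshold), centroid = NA_integer_,
                 synapse_type = synapse_type, input_mode = input_mode),
            class = "ade")
}

# Matched train/test split of the synthetic benchmark task.
synth_split <- function(n_classes, n_train, n_test, seed = 42, ...) {
  list(train = synth_image_set(n_classes, n_train, seed = seed,
                               dataset_seed = 1000L, ...),
       test = synth_image_set(n_classes, n_test, seed = seed,
                              dataset_seed = 2000L, ...))
}

# One small trained classifier, built once per test run and reused by the
# pipeline and kernel suites.
.toy_cache <- new.env(parent = emptyenv())
toy_model <- function() {
  if (is.null(.toy_cache$model)) {
    split <- synth_split(4, 30, 15, seed = 7)
    cfg <- preset_three_ad(w = 96, interval_t = 500,
                           unsupervised_presentations = 1500, seed = 5)
    .toy_cache$model <- sbc_classifier(split$train, cfg)
    .toy_cache$split <- split
  }
  list(model = .toy_cache$model, train = .toy_cache$split$train,
       test = .toy_cache$split$test)
}

# Brute-force oracle: write/read an SBC as explicit nested loops over
# (j, k, l). Independent of the packed implementation.
oracle_write <- function(arr3, row_pattern, col_pattern, label, layout) {
  for (j in row_pattern) for (k in col_pattern) {
    if (layout == "half" && !(j < k)) next
    arr3[j, k, label + 1L] <- TRUE
  }
  arr3
}
oracle_counts <- function(arr3, row_pattern, col_pattern, layout) {
  counts <- integer(dim(arr3)[3L])
  for (j in row_pattern) for (k in col_pattern) {
    if (layout == "half" && !(j < k)) next
    for (l in seq_len(dim(arr3)[3L])) {
      if (arr3[j, k, l]) counts[l] <- counts[l] + 1L
    }
  }
  counts
}
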