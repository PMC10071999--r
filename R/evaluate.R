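#' Evaluate a classifier on a labelled test set
#'
#' @param model a fitted `"sbc_classifier"`.
#' @param test_set a labelled [image_set()].
#' @return List with `accuracy` (fraction correct) and `confusion`
#'   (matrix with true classes on rows, predicted on columns).
#' @export
evaluate <- function(model, test_set) {
  stopifnot(inherits(test_set, "image_set"))
  if (n_images(test_set) == 0L) {
    stop("undefined accuracy: empty test set", call. = FALSE)
  }
  pred <- infer(model, test_set)$labels
  lv <- 0:(model$n_classes - 1L)
  confusion <- table(factor(test_set$labels, levels = lv),
                     factor(pred, levels = lv))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("true", "predicted")
  list(accuracy = mean(pred == test_set$labels), confusion = confusion)
}

#' Accuracy grid over training and test noise levels
#'
#' Trains one model per training noise level (with the noise frozen per
#' image) and evaluates it at every test noise level, reproducing the
#' robustness trade-off: training with noise costs a little accuracy on
#' clean inputs but protects against heavily corrupted ones.
#'
#' @param config an [sbc_config()]; its `train_noise` is overridden per
#'   grid row.
#' @param train_set,test_set labelled [image_set()]s.
#' @param train_levels,test_levels numeric noise levels (SD in pixels for
#'   gaussian; replacement probability for salt_pepper). Level 0 means no
#'   noise.
#' @param noise_kind `"gaussian"` or `"salt_pepper"`.
#' @param seed integer seed for the frozen noise realisations.
#' @return Numeric matrix of accuracies indexed `[train_level, test_level]`.
#' @export
noise_sweep <- function(config, train_set, test_set, train_levels,
                        test_levels, noise_kind = c("gaussian", "salt_pepper"),
                        seed = 1) {
  noise_kind <- match.arg(noise_kind)
  grid <- matrix(NA_real_, length(train_levels), length(test_levels),
                 dimnames = list(train = train_levels, test = test_levels))
  for (i in seq_along(train_levels)) {
    cfg <- config
    cfg$train_noise <- if (train_levels[i] > 0) {
      noise_spec(noise_kind, train_levels[i], derive_seed(seed, i))
    } else NULL
    model <- sbc_classifier(train_set, cfg)
    for (j in seq_along(test_levels)) {
      ts <- if (test_levels[j] > 0) {
        freeze_noise(test_set, noise_spec(noise_kind, test_levels[j],
                                          derive_seed(seed, 1000L + j)))
      } else test_set
      grid[i, j] <- evaluate(model, ts)$accuracy
    }
  }
  grid
}

#' Single-shot learning curve
#'
#' Measures accuracy as a function of the number of training examples per
#' class, from one example upwards. For each `n` the training set is
#' subsampled class-stratified without replacement (capped at the
#' available examples of each class, so under-represented classes are
#' exhausted first), the full pipeline is retrained, and the test accuracy
#' recorded over independent repeats.
#'
#' @inheritParams noise_sweep
#' @param per_class_ns integer vector of per-class training-set sizes.
#' @param repeats independent subsamples per size.
#' @param seed integer seed.
#' @return Data frame with columns `n_per_class`, `mean_accuracy`,
#'   `sd_accuracy`.
#' @export
single_shot_curve <- function(config, train_set, test_set, per_class_ns,
                              repeats = 3, seed = 1) {
  stopifnot(all(per_class_ns >= 1))
  res <- matrix(NA_real_, length(per_class_ns), repeats)
  by_class <- split(seq_len(n_images(train_set)), train_set$labels)
  for (i in seq_along(per_class_ns)) {
    n_per <- per_class_ns[i]
    for (r in seq_len(repeats)) {
      idx <- with_seed(derive_seed(seed, i * 1000L + r), function() {
        unlist(lapply(by_class, function(ix) {
          if (length(ix) <= n_per) ix else sample(ix, n_per)
        }), use.names = FALSE)
      })
      sub <- subset_images(train_set, sort(idx))
      sub$n_classes <- train_set$n_classes
      model <- sbc_classifier(sub, config)
      res[i, r] <- evaluate(model, test_set)$accuracy
    }
  }
  data.frame(n_per_class = per_class_ns,
             mean_accuracy = rowMeans(res),
             sd_accuracy = apply(res, 1L, function(x) {
               if (length(x) > 1L) stats::sd(x) else 0
             }))
}
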