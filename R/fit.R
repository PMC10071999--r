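#' Fit a sparse binary coincidence memory classifier
#'
#' Training runs in two phases. The unsupervised phase never reads labels:
#' the global pixel-mass distribution of the (optionally noise-frozen)
#' training images is accumulated, square-root transformed into the
#' sampling target, the address decoders are built by Metropolis-Hastings
#' synapse draws, and homeostatic threshold adaptation plus structural
#' plasticity drive every element toward the target firing probability.
#' The supervised phase is a single pass through the training set in
#' dataset order: for every example, every coincidence between firing
#' elements sets the example's class bit in the corresponding memory.
#' Because writes are idempotent ORs, the resulting bit state is
#' independent of training order and a second pass changes nothing.
#'
#' @param train_set an [image_set()] with labels.
#' @param config an [sbc_config()]; defaults to the three-decoder preset
#'   at desk scale (`w = 512`).
#' @return An object of class `"sbc_classifier"`: the configuration, the
#'   sampling target, the fitted decoders and the populated memories --
#'   sufficient for inference, with no training data retained.
#' @seealso [predict.sbc_classifier()], [evaluate()], [noise_sweep()],
#'   [single_shot_curve()]
#' @export
#' @examples
#' set <- synth_image_set(n_classes = 3, n_per_class = 30, seed = 1)
#' cfg <- preset_three_ad(w = 128, interval_t = 60, seed = 1)
#' fit <- sbc_classifier(set, cfg)
#' fit
sbc_classifier <- function(train_set, config = preset_three_ad(w = 512)) {
  stopifnot(inherits(train_set, "image_set"), inherits(config, "sbc_config"))
  if (n_images(train_set) < 1L) stop_invalid("empty training set")
  if (!is.null(config$train_noise)) {
    train_set <- freeze_noise(train_set, config$train_noise)
  }
  target <- sqrt_transform(accumulate_global_distribution(train_set))
  ads <- vector("list", length(config$ad_specs))
  for (k in seq_along(config$ad_specs)) {
    sp <- config$ad_specs[[k]]
    ads[[k]] <- build_address_decoder(target, sp$w, sp$n, sp$synapse_type,
                                      sp$locality_radius,
                                      seed = derive_seed(config$seed, 100L + k),
                                      input_mode = sp$input_mode)
  }
  n_pres <- config$unsupervised_presentations
  if (is.null(n_pres)) n_pres <- 2L * n_images(train_set)
  ads <- adapt_engine(ads, train_set, target = target,
                      n_presentations = n_pres,
                      target_rate = config$target_rate,
                      interval_t = config$interval_t, step = config$step,
                      plasticity = config$plasticity,
                      replace = config$plasticity, critical = config$critical,
                      seed = derive_seed(config$seed, 7L))
  plan <- config$sbc_plan
  sbcs <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    sbcs[[i]] <- create_sbc(plan$row[i], plan$col[i],
                            ads[[plan$row[i]]]$w, ads[[plan$col[i]]]$w,
                            train_set$n_classes, plan$layout[i])
  }
  model <- structure(
    list(config = config, target = target, ads = ads, sbcs = sbcs,
         n_classes = train_set$n_classes, image_shape = train_set$image_shape),
    class = "sbc_classifier"
  )
  supervised_pass(model, train_set)
}

#' Single-pass supervised population of the memories
#'
#' Writes the coincidence bits of every example of `set` into the model's
#' memories, in dataset order. Used by [sbc_classifier()] for the one
#' training pass; calling it again with the same noise-free data leaves
#' every bit identical (writes are idempotent), and calling it with new
#' labelled data implements continuous learning.
#'
#' @param model an `"sbc_classifier"`.
#' @param set a labelled [image_set()] of the training shape.
#' @return The model with updated memories.
#' @export
supervised_pass <- function(model, set) {
  check_shape(model, set)
  F <- firing_matrices(model, set)
  plan <- model$config$sbc_plan
  for (i in seq_len(n_images(set))) {
    label <- set$labels[i]
    for (s in seq_along(model$sbcs)) {
      model$sbcs[[s]] <- write_coincidences(
        model$sbcs[[s]],
        which(F[[plan$row[s]]][i, ]),
        which(F[[plan$col[s]]][i, ]),
        label
      )
    }
  }
  model
}

check_shape <- function(model, set) {
  if (!identical(as.integer(set$image_shape), as.integer(model$image_shape))) {
    stop_invalid("image shape %s does not match training shape %s",
                 paste(set$image_shape, collapse = "x"),
                 paste(model$image_shape, collapse = "x"))
  }
}

# One logical firing matrix (n_images x w) per decoder.
firing_matrices <- function(model, set) {
  X <- set_matrix(set)
  lapply(model$ads, function(ad) {
    ACT <- ad_activation_matrix(ad, X)
    ACT >= matrix(ad$threshold, nrow(ACT), ad$w, byrow = TRUE)
  })
}

#' Inference over a batch of images
#'
#' For every image the firing pattern of each decoder is computed once,
#' the set class bits are counted over the probed coincidence locations
#' of every memory, and the per-class counts are summed across memories.
#' The highest sum gives the inferred class (ties to the lowest class
#' index). Images activating no written location are flagged as carrying
#' no evidence and predicted as class 0.
#'
#' @param model a fitted `"sbc_classifier"`.
#' @param images an [image_set()] (labels optional and unread) or a
#'   `rows x cols x n` array.
#' @return List with `labels` (integer predictions), `counts`
#'   (`n x n_classes` matrix of summed bit counts) and `no_evidence`
#'   (logical vector).
#' @export
infer <- function(model, images) {
  if (!inherits(images, "image_set")) {
    images <- image_set(images, labels = rep(0L, dim(images)[3L]),
                        n_classes = model$n_classes)
  }
  check_shape(model, images)
  F <- firing_matrices(model, images)
  plan <- model$config$sbc_plan
  n <- n_images(images)
  counts <- matrix(0L, n, model$n_classes)
  for (i in seq_len(n)) {
    for (s in seq_along(model$sbcs)) {
      counts[i, ] <- counts[i, ] + read_counts(
        model$sbcs[[s]],
        which(F[[plan$row[s]]][i, ]),
        which(F[[plan$col[s]]][i, ])
      )
    }
  }
  labels <- max.col(counts, ties.method = "first") - 1L
  no_evidence <- rowSums(counts) == 0L
  labels[no_evidence] <- 0L
  list(labels = labels, counts = counts, no_evidence = no_evidence)
}

#' Predict method for SBC classifiers
#'
#' @param object a fitted `"sbc_classifier"`.
#' @param newdata an [image_set()] or `rows x cols x n` array.
#' @param type `"class"` for integer class labels (zero-based) or
#'   `"counts"` for the matrix of per-class summed bit counts.
#' @param ... unused.
#' @return Integer vector of labels or a counts matrix.
#' @export
predict.sbc_classifier <- function(object, newdata,
                                   type = c("class", "counts"), ...) {
  type <- match.arg(type)
  res <- infer(object, newdata)
  if (type == "class") res$labels else res$counts
}
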