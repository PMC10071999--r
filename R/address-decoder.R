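# Address decoders: ordered vectors of w address-decoder elements (ADEs).
# Each ADE subsamples n input pixels, computes activation = sum_i
# input_i * weight_i over its synapses, and fires when activation >= theta.
# Internal layout: w x n integer matrices `pixels`, `weights`, `longevity`;
# length-w integer vectors `threshold` and `centroid`.

LONGEVITY_DEFAULT <- 16L
LONGEVITY_CAP <- 255L

#' Build an address decoder
#'
#' Constructs `w` address-decoder elements of width `n`. Synapse pixels are
#' drawn from the Metropolis chain over the sampling target (so high-ink
#' pixels are sampled more often and blank corners essentially never),
#' subject to the locality and no-multapse constraints. Binary synapses get
#' weights of -1/+1 with equal probability; `"int8"` synapses get weights
#' uniform on `[-127, -1] U [1, 127]`. Longevities start at the default
#' (16) and thresholds at 0, pending homeostatic calibration.
#'
#' @inheritParams draw_ade_pixels
#' @param w number of elements in the decoder.
#' @param n synapses per element.
#' @param synapse_type `"binary"` (weights -1/+1 relating to synapse
#'   longevity) or `"int8"` (8-bit signed weights drawn uniformly).
#' @param input_mode `"greyscale"` (default: the centred pixel value
#'   multiplies the weight) or `"binary"` (the centred pixel is first
#'   binarised to its sign, 0 mapped to -1 -- the event-based variant that
#'   discards greyscale information at a small accuracy cost).
#' @return An object of class `"address_decoder"`.
#' @export
build_address_decoder <- function(target, w, n,
                                  synapse_type = c("binary", "int8"),
                                  locality_radius = NULL, seed = 1,
                                  max_rejects = 10000L,
                                  locality_mode = c("centroid", "any"),
                                  input_mode = c("greyscale", "binary")) {
  synapse_type <- match.arg(synapse_type)
  input_mode <- match.arg(input_mode)
  locality_mode <- match.arg(locality_mode)
  w <- as.integer(w); n <- as.integer(n)
  if (w < 1L || n < 1L) stop_invalid("w and n must be >= 1")
  with_seed(seed, function() {
    ch <- mh_new_chain(target)
    pixels <- matrix(0L, w, n)
    centroid <- integer(w)
    for (j in seq_len(w)) {
      d <- draw_ade_pixels_chain(ch, n, locality_radius, as.integer(max_rejects),
                                 locality_mode)
      pixels[j, ] <- d$pixels
      centroid[j] <- d$centroid
    }
    weights <- if (synapse_type == "binary") {
      matrix(sample(c(-1L, 1L), w * n, replace = TRUE), w, n)
    } else {
      matrix(sample(c(-127:-1, 1:127), w * n, replace = TRUE), w, n)
    }
    structure(
      list(pixels = pixels, weights = weights,
           longevity = matrix(LONGEVITY_DEFAULT, w, n),
           threshold = integer(w), centroid = centroid,
           w = w, n = n, synapse_type = synapse_type,
           input_mode = input_mode, locality_radius = locality_radius,
           image_shape = target$image_shape),
      class = "address_decoder"
    )
  })
}

#' @export
print.address_decoder <- function(x, ...) {
  cat(sprintf("<address_decoder> w = %d elements, n = %d synapses (%s weights, %s inputs), locality r = %s\n",
              x$w, x$n, x$synapse_type, x$input_mode,
              if (is.null(x$locality_radius)) "none" else x$locality_radius))
  invisible(x)
}

#' Extract one address-decoder element
#'
#' @param ad an [build_address_decoder()] object.
#' @param j element index in `[1, w]`.
#' @return A list of class `"ade"` with `pixels`, `weights`, `longevity`,
#'   `threshold`, `centroid`, `synapse_type` and `input_mode`.
#' @export
ad_element <- function(ad, j) {
  stopifnot(inherits(ad, "address_decoder"), j >= 1L, j <= ad$w)
  structure(list(pixels = ad$pixels[j, ], weights = ad$weights[j, ],
                 longevity = ad$longevity[j, ], threshold = ad$threshold[j],
                 centroid = ad$centroid[j], synapse_type = ad$synapse_type,
                 input_mode = ad$input_mode),
            class = "ade")
}

# Flatten a centred image to the decoder input vector: the centred value
# itself in greyscale mode, or its sign (0 -> -1) in binary input mode.
decoder_input <- function(image, input_mode) {
  x <- as.integer(image)
  if (input_mode == "binary") ifelse(x > 0L, 1L, -1L) else x
}

#' Activation of a single element
#'
#' Computes `sum_i input_i * weight_i` over the element's synapses, where
#' `input` is the centred image (see [center_pixels()]). In binary input
#' mode the centred input is first binarised by sign (0 maps to -1).
#'
#' @param ade an element from [ad_element()].
#' @param image centred image: integer matrix or vector with values in
#'   `[-127, 128]`.
#' @return A single integer activation.
#' @export
ade_activation <- function(ade, image) {
  x <- decoder_input(image, ade$input_mode)
  sum(x[ade$pixels] * ade$weights)
}

# Length-w activation vector for a whole decoder on one centred image.
decoder_activations <- function(ad, image) {
  x <- decoder_input(image, ad$input_mode)
  as.integer(rowSums(matrix(x[ad$pixels], ad$w, ad$n) * ad$weights))
}

# Dense (n_pixels x w) weight-scatter matrix: column j holds ADE j's
# weights at its synapse pixels (no multapses, so no collisions).
# activations over many images = X %*% S in one BLAS call.
ad_weight_matrix <- function(ad, n_pixels) {
  S <- matrix(0, n_pixels, ad$w)
  S[cbind(as.vector(ad$pixels), rep(seq_len(ad$w), times = ad$n))] <-
    as.double(ad$weights)
  S
}

# Activation matrix (n_images x w) from a raw pixel matrix X_raw
# (n_images x n_pixels, values 0..255).
ad_activation_matrix <- function(ad, X_raw) {
  Xc <- X_raw - 127
  X <- if (ad$input_mode == "binary") (Xc > 0) * 2 - 1 else Xc
  X %*% ad_weight_matrix(ad, ncol(X_raw))
}

#' Firing pattern of a decoder
#'
#' @inheritParams ade_activation
#' @param ad an address decoder.
#' @return Sorted integer vector of firing element indices: those with
#'   `activation >= threshold` (the inequality is inclusive).
#' @export
decoder_firing_pattern <- function(ad, image) {
  act <- decoder_activations(ad, image)
  which(act >= ad$threshold)
}

#' Per-element firing rates over a full sweep of a set
#'
#' @param ad an address decoder.
#' @param set an [image_set()]; labels are not read.
#' @return Numeric vector of length `w`: the fraction of images on which
#'   each element fired.
#' @export
decoder_firing_rates <- function(ad, set) {
  ACT <- ad_activation_matrix(ad, set_matrix(set))
  colMeans(ACT >= matrix(ad$threshold, nrow(ACT), ad$w, byrow = TRUE))
}

#' Per-synapse Hebbian plasticity after a firing event
#'
#' Given an element that fired on this input, the synapse contributing
#' least to the activation sum (signed contribution `input_i * weight_i`)
#' has its longevity decremented by 1 (floor 0) and the largest contributor
#' is incremented by 1 (ceiling 255). Ties go to the lowest synapse
#' position; if the same synapse is both argmin and argmax, nothing
#' changes.
#'
#' @inheritParams ade_activation
#' @return The updated element. Calling it on an element that did not fire
#'   on `image` is a contract violation and errors.
#' @export
plasticity_step <- function(ade, image) {
  x <- decoder_input(image, ade$input_mode)
  contrib <- x[ade$pixels] * ade$weights
  if (sum(contrib) < ade$threshold) {
    stop("contract violation: plasticity_step called on a non-firing element",
         call. = FALSE)
  }
  imin <- which.min(contrib)
  imax <- which.max(contrib)
  if (imin != imax) {
    ade$longevity[imin] <- max(0L, ade$longevity[imin] - 1L)
    ade$longevity[imax] <- min(LONGEVITY_CAP, ade$longevity[imax] + 1L)
  }
  ade
}

# Vectorised plasticity over the firing set `fired` (indices) of one
# decoder for the raw input row x_raw; mirrors plasticity_step exactly.
apply_plasticity <- function(ad, fired, x_raw) {
  if (length(fired) == 0L) return(ad)
  x <- decoder_input(x_raw - 127L, ad$input_mode)
  Cm <- matrix(x[ad$pixels[fired, , drop = FALSE]], length(fired), ad$n) *
    ad$weights[fired, , drop = FALSE]
  imax <- max.col(Cm, ties.method = "first")
  imin <- max.col(-Cm, ties.method = "first")
  keep <- imin != imax
  if (any(keep)) {
    jd <- cbind(fired[keep], imin[keep])
    ju <- cbind(fired[keep], imax[keep])
    ad$longevity[jd] <- pmax(0L, ad$longevity[jd] - 1L)
    ad$longevity[ju] <- pmin(LONGEVITY_CAP, ad$longevity[ju] + 1L)
  }
  ad
}

#' Replace persistently under-contributing synapses
#'
#' Every synapse whose longevity has fallen below `critical` is replaced by
#' a fresh Metropolis draw from the sampling target, respecting the
#' element's original centroid, the locality radius and the no-multapse
#' rule. The new synapse gets a redrawn weight and the default longevity.
#'
#' @inheritParams build_address_decoder
#' @param ad an address decoder.
#' @param critical longevity threshold below which a synapse is replaced.
#' @return The updated decoder (unchanged if no synapse is weak).
#' @export
replace_weak_synapses <- function(ad, target, critical = 1L, seed = 1,
                                  max_rejects = 10000L) {
  weak <- which(ad$longevity < critical, arr.ind = TRUE)
  if (nrow(weak) == 0L) return(ad)
  with_seed(seed, function() {
    ch <- mh_new_chain(target)
    replace_weak_synapses_chain(ad, ch, critical, as.integer(max_rejects))
  })
}

# Same, but on an existing chain using the ambient RNG (engine path).
replace_weak_synapses_chain <- function(ad, ch, critical, max_rejects) {
  weak <- which(ad$longevity < critical, arr.ind = TRUE)
  if (nrow(weak) == 0L) return(ad)
  nr <- ch$nr
  r <- ad$locality_radius
  for (k in seq_len(nrow(weak))) {
    j <- weak[k, 1L]; i <- weak[k, 2L]
    cen <- ad$centroid[j]
    cen_r <- ((cen - 1L) %% nr) + 1L
    cen_c <- ((cen - 1L) %/% nr) + 1L
    rejects <- 0L
    repeat {
      cand <- mh_step(ch)
      ok <- !(cand %in% ad$pixels[j, -i])
      if (ok && !is.null(r)) {
        cr <- ((cand - 1L) %% nr) + 1L
        cc <- ((cand - 1L) %/% nr) + 1L
        ok <- abs(cr - cen_r) <= r && abs(cc - cen_c) <= r
      }
      if (ok) break
      rejects <- rejects + 1L
      if (rejects > max_rejects) {
        stop(sprintf("sampling exhausted replacing synapse %d of element %d (centroid pixel %d)",
                     i, j, cen), call. = FALSE)
      }
    }
    ad$pixels[j, i] <- cand
    ad$weights[j, i] <- if (ad$synapse_type == "binary") {
      sample(c(-1L, 1L), 1L)
    } else {
      sample(c(-127:-1, 1:127), 1L)
    }
    ad$longevity[j, i] <- LONGEVITY_DEFAULT
  }
  ad
}

# --- unsupervised learning engine -----------------------------------------
#
# Presentations are drawn randomly with replacement (avoiding order biases)
# and processed interval by interval. Within an interval thresholds and
# synapses are fixed, so activations for the whole interval are computed in
# one matrix product per decoder. At each interval boundary:
#   * first interval (calibration): threshold_j is set to the
#     ceil(target_rate * t)-th largest activation seen, starting the chain
#     near the target rate;
#   * later intervals: the firing count is compared with
#     target_rate * t; counts outside a +/-25% dead band move the
#     threshold by +/-step (up if too many firings);
#   * synapses with longevity < critical are replaced (when enabled).
# Longevity plasticity runs per firing event inside the interval. Labels
# are never read.

adapt_engine <- function(ads, set, target = NULL, n_presentations,
                         target_rate = 0.01, interval_t = 2000L, step = 1L,
                         plasticity = TRUE, replace = TRUE, critical = 1L,
                         seed = 1, deadband = 0.25, max_rejects = 10000L) {
  interval_t <- as.integer(interval_t)
  n_presentations <- as.integer(n_presentations)
  if (target_rate <= 0 || target_rate >= 1) stop_invalid("target_rate must lie in (0, 1)")
  if (interval_t < 1L) stop_invalid("interval_t must be >= 1")
  if (n_images(set) < 1L) stop_invalid("empty presentation stream")
  if (n_presentations == 0L) return(ads)
  X_raw <- set_matrix(set)
  step <- as.integer(step)
  with_seed(seed, function() {
    ch <- if (replace && !is.null(target)) mh_new_chain(target) else NULL
    pres <- sample.int(nrow(X_raw), n_presentations, replace = TRUE)
    starts <- seq(1L, n_presentations, by = interval_t)
    first_interval <- rep(TRUE, length(ads))
    for (s in starts) {
      idx <- pres[s:min(s + interval_t - 1L, n_presentations)]
      full <- length(idx) == interval_t
      Xb <- X_raw[idx, , drop = FALSE]
      for (a in seq_along(ads)) {
        ad <- ads[[a]]
        ACT <- ad_activation_matrix(ad, Xb)
        FIRE <- ACT >= matrix(ad$threshold, nrow(ACT), ad$w, byrow = TRUE)
        # no plasticity during the calibration interval: before the
        # threshold is set, "firing" does not identify a feature
        if (plasticity && !(first_interval[a] && step != 0L)) {
          for (p in which(rowSums(FIRE) > 0L)) {
            ad <- apply_plasticity(ad, which(FIRE[p, ]), Xb[p, ])
          }
        }
        if (step != 0L && full) {
          k <- max(1L, as.integer(round(target_rate * interval_t)))
          # smallest achievable |firing count - target|: candidate cuts are
          # the distinct activation values (count = #act >= cut, inclusive
          # firing) plus one above the maximum (count 0). Integer
          # activations carry atoms -- e.g. the exact constant an element
          # sees whenever its whole pixel cluster is background -- so a
          # plain k-th order statistic can land on an atom and overshoot
          # the target rate by orders of magnitude; ties prefer the higher
          # cut (sparser firing).
          best_cut <- function(cols) {
            vapply(cols, function(j) {
              col <- ACT[, j]
              u <- sort(unique(col), decreasing = TRUE)
              cum <- cumsum(tabulate(match(col, u), nbins = length(u)))
              cand_theta <- c(u[1L] + 1, u)
              cand_theta[which.min(abs(c(0, cum) - k))]
            }, numeric(1))
          }
          if (first_interval[a]) {
            ad$threshold <- as.integer(best_cut(seq_len(ad$w)))
            first_interval[a] <- FALSE
          } else {
            counts <- colSums(FIRE)
            tc <- target_rate * interval_t
            adjust <- counts > tc * (1 + deadband) | counts < tc * (1 - deadband)
            if (any(adjust)) {
              ad$threshold[adjust] <- as.integer(best_cut(which(adjust)))
            }
          }
        }
        # no replacement after the final interval: a freshly drawn synapse
        # shifts the element's activation scale and needs at least one
        # further interval of threshold re-tracking to be calibrated
        last_boundary <- s + interval_t - 1L >= n_presentations
        if (replace && !is.null(ch) && full && !last_boundary) {
          ad <- replace_weak_synapses_chain(ad, ch, as.integer(critical),
                                            as.integer(max_rejects))
        }
        ads[[a]] <- ad
      }
    }
    ads
  })
}

#' Homeostatic threshold adaptation
#'
#' Presents randomly drawn images (with replacement) to the decoder and
#' adapts every element's threshold toward a target firing probability.
#' Firing events are accumulated over intervals of `interval_t`
#' presentations; at each interval boundary a count above/below the target
#' count moves the threshold up/down by `step` (with a 25% dead band to
#' avoid limit-cycle thrash). The first interval calibrates each threshold
#' to the empirical `(1 - target_rate)` activation quantile. With
#' `step = 0` thresholds are left untouched.
#'
#' @param ad an address decoder.
#' @param set an [image_set()] supplying the presentation stream (labels
#'   are never read).
#' @param target_rate target firing probability per element, in `(0, 1)`.
#' @param interval_t presentations per adaptation interval.
#' @param step integer threshold increment.
#' @param n_presentations total presentations; defaults to twice the set
#'   size.
#' @param seed integer seed for the presentation order.
#' @return The decoder with adapted thresholds (synapses untouched).
#' @export
adapt_thresholds <- function(ad, set, target_rate = 0.01, interval_t = 2000L,
                             step = 1L, n_presentations = NULL, seed = 1) {
  if (is.null(n_presentations)) n_presentations <- 2L * n_images(set)
  adapt_engine(list(ad), set, target = NULL,
               n_presentations = n_presentations, target_rate = target_rate,
               interval_t = interval_t, step = step, plasticity = FALSE,
               replace = FALSE, seed = seed)[[1L]]
}

#' Unsupervised learning over a set of decoders
#'
#' Orchestrates homeostatic threshold adaptation, per-firing longevity
#' plasticity and interval-boundary replacement of weak synapses over one
#' randomly drawn presentation schedule shared by all decoders. Class
#' labels are never read.
#'
#' @inheritParams adapt_thresholds
#' @param ads list of address decoders.
#' @param target sampling target used to redraw replaced synapses;
#'   computed from `set` when `NULL`.
#' @param plasticity logical; disable to adapt thresholds only.
#' @param replace logical; disable to keep all synapses.
#' @param critical longevity below which a synapse is replaced.
#' @return The list of updated decoders.
#' @export
unsupervised_learn <- function(ads, set, target = NULL,
                               n_presentations = NULL, target_rate = 0.01,
                               interval_t = 2000L, step = 1L,
                               plasticity = TRUE, replace = TRUE,
                               critical = 1L, seed = 1) {
  if (is.null(n_presentations)) n_presentations <- 2L * n_images(set)
  if (is.null(target) && replace) {
    target <- sqrt_transform(accumulate_global_distribution(set))
  }
  adapt_engine(ads, set, target = target, n_presentations = n_presentations,
               target_rate = target_rate, interval_t = interval_t,
               step = step, plasticity = plasticity, replace = replace,
               critical = critical, seed = seed)
}
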