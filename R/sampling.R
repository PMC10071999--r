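#' Accumulate the global pixel-mass distribution
#'
#' Sums every pixel value of the training images into one bin per input
#' dimension (784 bins for 28 x 28 rasters), in double precision so no
#' accumulator can overflow. Bin `p` corresponds to the column-major
#' flattened pixel index `(col - 1) * rows + row`.
#'
#' @param images an [image_set()], a `rows x cols x n` array, or a list of
#'   matrices of raw pixel values.
#' @return An object of class `"pixel_mass"`: list with `mass`
#'   (nonnegative numeric vector) and `image_shape`.
#' @export
accumulate_global_distribution <- function(images) {
  if (inherits(images, "image_set")) {
    arr <- images$images
  } else if (is.list(images)) {
    arr <- image_set(images, labels = rep(0L, length(images)), n_classes = 1L)$images
  } else {
    arr <- images
  }
  if (!is.array(arr) || length(dim(arr)) != 3L || dim(arr)[3L] < 1L) {
    stop_invalid("need at least one image of consistent shape")
  }
  d <- dim(arr)
  mass <- rowSums(matrix(as.double(arr), d[1L] * d[2L], d[3L]))
  structure(list(mass = mass, image_shape = d[1:2]), class = "pixel_mass")
}

#' Square-root transform of the pixel-mass vector
#'
#' Takes the elementwise square root of the accumulated pixel mass,
#' flattening the distribution so that synapses can also be drawn slightly
#' outside the densest ink regions. No normalisation is applied: the
#' Metropolis sampler only needs relative probabilities, and the bins are
#' Poisson-like counts whose square root is approximately homoscedastic.
#'
#' @param mass a `"pixel_mass"` object from
#'   [accumulate_global_distribution()].
#' @return An object of class `"sampling_target"`: list with
#'   `relative_mass` and `image_shape`.
#' @export
sqrt_transform <- function(mass) {
  stopifnot(inherits(mass, "pixel_mass"))
  structure(list(relative_mass = sqrt(mass$mass), image_shape = mass$image_shape),
            class = "sampling_target")
}

# --- Metropolis-Hastings machinery ----------------------------------------
#
# Random-walk Metropolis on the 2D pixel grid. The proposal is uniform over
# the 7x7 offset box around the current pixel, excluding (0,0); offsets that
# leave the image are re-proposed, which makes the effective proposal
# uniform over the n_valid(x) in-bounds non-zero offsets. Because n_valid
# differs near borders, the acceptance ratio carries the Hastings correction
#   min(1, T(y) * n_valid(x) / (T(x) * n_valid(y)))
# so the stationary law is exactly T / sum(T). The chain starts at the
# argmax pixel and discards the first `burn_in` steps. Proposals onto
# zero-mass pixels are always rejected, so after burn-in the chain never
# emits a zero-mass pixel. Consecutive retained states may repeat (standard
# Metropolis; duplicates are filtered later by multapse rejection).

mh_new_chain <- function(target, burn_in = 1000L) {
  stopifnot(inherits(target, "sampling_target"))
  tm <- target$relative_mass
  if (all(tm <= 0)) stop_invalid("sampling target has no positive mass")
  nr <- target$image_shape[1L]; nc <- target$image_shape[2L]
  Tm <- matrix(tm, nr, nc)
  vr <- pmin(seq_len(nr) + 3L, nr) - pmax(seq_len(nr) - 3L, 1L) + 1L
  vc <- pmin(seq_len(nc) + 3L, nc) - pmax(seq_len(nc) - 3L, 1L) + 1L
  nvalid <- outer(vr, vc) - 1L
  start <- arrayInd(which.max(Tm), dim(Tm))
  ch <- new.env(parent = emptyenv())
  ch$Tm <- Tm; ch$nvalid <- nvalid; ch$nr <- nr; ch$nc <- nc
  ch$r <- start[1L]; ch$c <- start[2L]
  for (i in seq_len(burn_in)) mh_step(ch)
  ch
}

# One Metropolis step; returns the (possibly unchanged) state as a
# column-major pixel index.
mh_step <- function(ch) {
  nr <- ch$nr; nc <- ch$nc; r <- ch$r; c <- ch$c
  repeat {
    dr <- sample.int(7L, 1L) - 4L
    dc <- sample.int(7L, 1L) - 4L
    if (dr == 0L && dc == 0L) next
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) break
  }
  t_new <- ch$Tm[r2, c2]
  if (t_new > 0) {
    a <- (t_new * ch$nvalid[r, c]) / (ch$Tm[r, c] * ch$nvalid[r2, c2])
    if (a >= 1 || stats::runif(1L) < a) { ch$r <- r2; ch$c <- c2 }
  }
  (ch$c - 1L) * nr + ch$r
}

#' Draw pixel indices by Metropolis-Hastings sampling
#'
#' Runs the random-walk Metropolis chain on the (unnormalised) sampling
#' target and returns `n_draws` retained states after a burn-in of 1,000
#' steps. The empirical law of the draws converges to
#' `target / sum(target)`.
#'
#' @param target a `"sampling_target"` from [sqrt_transform()].
#' @param n_draws number of retained draws.
#' @param seed integer seed; the chain is deterministic given the seed.
#' @return Integer vector of column-major pixel indices (1-based).
#' @export
mh_chain <- function(target, n_draws, seed = 1) {
  n_draws <- as.integer(n_draws)
  with_seed(seed, function() {
    ch <- mh_new_chain(target)
    out <- integer(n_draws)
    for (i in seq_len(n_draws)) out[i] <- mh_step(ch)
    out
  })
}

# Draw a centroid plus n unique synapse pixels from an existing chain.
# Locality: candidate accepted only within Chebyshev distance `radius` of
# the centroid (mode "centroid") or of any already-accepted pixel (mode
# "any"); multapses (repeated pixels) are rejected. `max_rejects` bounds
# the rejections per synapse so exhaustion fails deterministically.
draw_ade_pixels_chain <- function(ch, n, radius = NULL, max_rejects = 10000L,
                                  locality_mode = c("centroid", "any")) {
  locality_mode <- match.arg(locality_mode)
  nr <- ch$nr
  centroid <- mh_step(ch)
  cen_r <- ((centroid - 1L) %% nr) + 1L
  cen_c <- ((centroid - 1L) %/% nr) + 1L
  pixels <- integer(n)
  for (i in seq_len(n)) {
    rejects <- 0L
    repeat {
      cand <- mh_step(ch)
      ok <- !(cand %in% pixels[seq_len(i - 1L)])
      if (ok && !is.null(radius)) {
        cr <- ((cand - 1L) %% nr) + 1L
        cc <- ((cand - 1L) %/% nr) + 1L
        if (locality_mode == "centroid" || i == 1L) {
          ok <- abs(cr - cen_r) <= radius && abs(cc - cen_c) <= radius
        } else {
          prev <- pixels[seq_len(i - 1L)]
          pr <- ((prev - 1L) %% nr) + 1L
          pc <- ((prev - 1L) %/% nr) + 1L
          ok <- any(abs(cr - c(cen_r, pr)) <= radius & abs(cc - c(cen_c, pc)) <= radius)
        }
      }
      if (ok) { pixels[i] <- cand; break }
      rejects <- rejects + 1L
      if (rejects > max_rejects) {
        stop(sprintf("sampling exhausted: %d rejections drawing synapse %d (centroid pixel %d)",
                     rejects, i, centroid), call. = FALSE)
      }
    }
  }
  list(centroid = centroid, pixels = pixels)
}

#' Draw the pixel set for one address-decoder element
#'
#' Draws a centroid from the Metropolis chain over the sampling target,
#' then `n` distinct synapse pixels from the same chain, each rejected
#' until it falls within the `(2r+1)^2` Chebyshev box around the centroid
#' (when `locality_radius` is set) and is not already used by this element
#' (multapses are disallowed).
#'
#' @inheritParams mh_chain
#' @param n number of synapse pixels (the element width).
#' @param locality_radius Chebyshev radius `r` of the locality box, or
#'   `NULL` for no spatial constraint.
#' @param max_rejects rejection budget per synapse before a deterministic
#'   sampling-exhausted error.
#' @param locality_mode `"centroid"` (default; spherical detectors) or
#'   `"any"` (distance measured from any already-chosen pixel, allowing
#'   elongated detectors).
#' @return List with `centroid` (pixel index) and `pixels` (integer vector
#'   of `n` distinct pixel indices).
#' @export
draw_ade_pixels <- function(target, n, locality_radius = NULL, seed = 1,
                            max_rejects = 10000L,
                            locality_mode = c("centroid", "any")) {
  locality_mode <- match.arg(locality_mode)
  with_seed(seed, function() {
    ch <- mh_new_chain(target)
    draw_ade_pixels_chain(ch, as.integer(n), locality_radius,
                          as.integer(max_rejects), locality_mode)
  })
}
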