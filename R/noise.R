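#' Centre 8-bit pixels either side of zero
#'
#' Subtracts 127 from the raw unsigned pixel values, producing a bipolar
#' input in `[-127, 128]` suitable for multiplication by signed synaptic
#' weights. This is the only preprocessing applied before the decoders.
#'
#' @param image integer matrix of raw pixel values in `[0, 255]`.
#' @return Integer matrix of the same shape with values in `[-127, 128]`.
#' @export
#' @examples
#' center_pixels(matrix(c(0L, 127L, 255L), 1))
center_pixels <- function(image) {
  if (anyNA(image) || min(image) < 0L || max(image) > 255L) {
    stop_invalid("pixels must lie in [0, 255]")
  }
  image - 127L
}

#' Noise specifications
#'
#' Describes one of the two pixel corruption models, on the raw 0--255
#' scale: additive Gaussian noise of a given SD clamped at 0 and 255, or
#' salt-and-pepper replacement (each corrupted pixel becomes 0 or 255 with
#' equal probability).
#'
#' @param kind `"none"`, `"gaussian"` or `"salt_pepper"`.
#' @param level SD in pixel units (gaussian) or replacement probability in
#'   `[0, 1]` (salt_pepper).
#' @param seed integer seed keying the frozen noise realisation.
#' @return A list of class `"noise_spec"`.
#' @export
noise_spec <- function(kind = c("none", "gaussian", "salt_pepper"),
                       level = 0, seed = 0) {
  kind <- match.arg(kind)
  if (kind == "gaussian" && level < 0) stop_invalid("gaussian level must be >= 0")
  if (kind == "salt_pepper" && (level < 0 || level > 1)) {
    stop_invalid("salt_pepper level must lie in [0, 1]")
  }
  structure(list(kind = kind, level = level, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add clamped Gaussian noise to a raw image
#'
#' Adds i.i.d. `N(0, sd)` noise to each raw 8-bit pixel, rounds to the
#' nearest integer (ties away from zero) and clamps to `[0, 255]`.
#'
#' @param image integer matrix of raw pixels.
#' @param sd noise standard deviation in pixel units (>= 0).
#' @param seed integer seed; output is deterministic given the seed.
#' @return Integer matrix of valid raw pixels.
#' @export
add_gaussian_noise <- function(image, sd, seed = 0) {
  if (sd < 0) stop_invalid("sd must be >= 0")
  if (sd == 0) return(image)
  with_seed(seed, function() {
    noisy <- round_half_away(image + stats::rnorm(length(image), 0, sd))
    out <- pmin(255, pmax(0, noisy))
    storage.mode(out) <- "integer"
    dim(out) <- dim(image)
    out
  })
}

#' Add salt-and-pepper noise to a raw image
#'
#' Each pixel is independently replaced with probability `p`; the
#' replacement value is 0 or 255, each with probability one half.
#'
#' @inheritParams add_gaussian_noise
#' @param p replacement probability in `[0, 1]`.
#' @return Integer matrix of valid raw pixels.
#' @export
add_salt_pepper <- function(image, p, seed = 0) {
  if (p < 0 || p > 1) stop_invalid("p must lie in [0, 1]")
  if (p == 0) return(image)
  with_seed(seed, function() {
    hit <- stats::runif(length(image)) < p
    salt <- stats::runif(length(image)) < 0.5
    out <- image
    out[hit] <- ifelse(salt[hit], 255L, 0L)
    storage.mode(out) <- "integer"
    dim(out) <- dim(image)
    out
  })
}

#' Apply one frozen noise realisation per image
#'
#' Draws exactly one noise pattern per training image, keyed by
#' `(spec$seed, image index)`, so the same spec always reproduces the
#' identical corrupted set ("static" noise). Each image is therefore seen
#' with a single realisation regardless of how many passes consume it.
#'
#' @param set an [image_set()].
#' @param spec a [noise_spec()].
#' @return An [image_set()] with the same labels.
#' @export
freeze_noise <- function(set, spec) {
  stopifnot(inherits(set, "image_set"), inherits(spec, "noise_spec"))
  if (spec$kind == "none") return(set)
  imgs <- set$images
  for (i in seq_len(n_images(set))) {
    s <- derive_seed(spec$seed, i)
    imgs[, , i] <- switch(spec$kind,
      gaussian = add_gaussian_noise(set$images[, , i], spec$level, s),
      salt_pepper = add_salt_pepper(set$images[, , i], spec$level, s)
    )
  }
  image_set(imgs, set$labels, set$n_classes)
}
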