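#' Address-decoder specification
#'
#' @param n element width (synapses per element).
#' @param w number of elements.
#' @param locality_radius Chebyshev locality radius; the default maps the
#'   widths 6, 8, 10, 12 to radii 2, 3, 3, 4 (`round(n / 3)` clamped to
#'   `[2, 4]`).
#' @param synapse_type `"binary"` or `"int8"` weights.
#' @param input_mode `"greyscale"` (centred pixel values) or `"binary"`
#'   (sign-binarised inputs).
#' @return A list of class `"ad_spec"`.
#' @export
ad_spec <- function(n, w = 2048, locality_radius = default_radius(n),
                    synapse_type = c("binary", "int8"),
                    input_mode = c("greyscale", "binary")) {
  synapse_type <- match.arg(synapse_type)
  input_mode <- match.arg(input_mode)
  structure(list(n = as.integer(n), w = as.integer(w),
                 locality_radius = if (is.null(locality_radius)) NULL else as.integer(locality_radius),
                 synapse_type = synapse_type, input_mode = input_mode),
            class = "ad_spec")
}

#' @rdname ad_spec
#' @export
default_radius <- function(n) {
  max(2L, min(4L, as.integer(round(n / 3))))
}

# Expand a plan keyword into an explicit (row, col, layout) table.
# "all_pairs": one full-size memory per unordered pair of distinct
# decoders. "all_pairs_plus_half": the same plus one half-size
# within-decoder memory per decoder.
expand_sbc_plan <- function(plan, n_ads) {
  if (is.data.frame(plan)) {
    stopifnot(all(c("row", "col", "layout") %in% names(plan)))
    if (any(plan$row > n_ads | plan$col > n_ads | plan$row < 1 | plan$col < 1)) {
      stop_invalid("sbc plan references a decoder that does not exist")
    }
    if (any(plan$layout == "half" & plan$row != plan$col)) {
      stop_invalid("half-size memories must pair a decoder with itself")
    }
    return(plan)
  }
  pairs <- if (n_ads >= 2L) utils::combn(n_ads, 2L) else matrix(integer(0), 2, 0)
  full <- data.frame(row = pairs[1L, ], col = pairs[2L, ],
                     layout = rep("full", ncol(pairs)))
  switch(plan,
    all_pairs = full,
    all_pairs_plus_half = rbind(full,
      data.frame(row = seq_len(n_ads), col = seq_len(n_ads),
                 layout = rep("half", n_ads))),
    stop_invalid("unknown sbc plan '%s'", plan)
  )
}

#' Classifier configuration
#'
#' @param ad_specs list of [ad_spec()] objects.
#' @param sbc_plan `"all_pairs_plus_half"`, `"all_pairs"`, or an explicit
#'   data frame with columns `row`, `col`, `layout`.
#' @param target_rate homeostatic target firing probability per element.
#' @param interval_t presentations per adaptation interval.
#' @param unsupervised_presentations total unsupervised presentations;
#'   `NULL` means twice the training-set size.
#' @param step threshold adaptation step.
#' @param plasticity enable longevity plasticity and synapse replacement.
#' @param critical longevity below which a synapse is replaced.
#' @param train_noise optional [noise_spec()] applied frozen to the
#'   training set before both learning phases.
#' @param seed master seed; all internal seeds are derived from it.
#' @return A list of class `"sbc_config"`.
#' @export
sbc_config <- function(ad_specs, sbc_plan = "all_pairs_plus_half",
                       target_rate = 0.01, interval_t = 2000,
                       unsupervised_presentations = NULL, step = 1,
                       plasticity = TRUE, critical = 1,
                       train_noise = NULL, seed = 1) {
  stopifnot(length(ad_specs) >= 1L,
            all(vapply(ad_specs, inherits, logical(1), "ad_spec")))
  plan <- expand_sbc_plan(sbc_plan, length(ad_specs))
  structure(list(ad_specs = ad_specs, sbc_plan = plan,
                 target_rate = target_rate, interval_t = as.integer(interval_t),
                 unsupervised_presentations = unsupervised_presentations,
                 step = as.integer(step), plasticity = isTRUE(plasticity),
                 critical = as.integer(critical), train_noise = train_noise,
                 seed = as.integer(seed)),
            class = "sbc_config")
}

#' Preset configurations
#'
#' `preset_four_ad()` is the benchmark setup: four decoders with element
#' widths 6, 8, 10, 12 (locality radii 2, 3, 3, 4) and ten memories -- six
#' full-size between distinct decoders plus four half-size within-decoder
#' memories. `preset_three_ad()` is the lighter setup: three decoders with
#' widths 6, 10, 12 (radii 2, 3, 4) and three full-size memories only.
#'
#' @param w elements per decoder (2,048 in the benchmark setup; smaller
#'   values are convenient for desk-scale experiments).
#' @param ... passed on to [sbc_config()].
#' @return An [sbc_config()].
#' @export
preset_four_ad <- function(w = 2048, ...) {
  sbc_config(lapply(c(6L, 8L, 10L, 12L), ad_spec, w = w),
             sbc_plan = "all_pairs_plus_half", ...)
}

#' @rdname preset_four_ad
#' @export
preset_three_ad <- function(w = 2048, ...) {
  sbc_config(lapply(c(6L, 10L, 12L), ad_spec, w = w),
             sbc_plan = "all_pairs", ...)
}

#' Size of the unrolled coincidence space
#'
#' Total number of addressable coincidence locations across all memories
#' of a plan: `w_row * w_col` for a full-size memory and
#' `w * (w - 1) / 2` for a half-size one. Three full-size memories over
#' decoders of width 2,048 give `3 * 2048^2 = 12,582,912`.
#'
#' @param x an `"sbc_config"`, a fitted `"sbc_classifier"`, or a plan data
#'   frame (then `widths` is required).
#' @param widths integer vector of decoder widths (one per decoder).
#' @return A double: the unrolled bit-vector length `m`.
#' @export
coincidence_space_size <- function(x, widths = NULL) {
  if (inherits(x, "sbc_classifier")) {
    return(sum(vapply(x$sbcs, sbc_addressable, numeric(1))))
  }
  if (inherits(x, "sbc_config")) {
    widths <- vapply(x$ad_specs, function(s) as.numeric(s$w), numeric(1))
    x <- x$sbc_plan
  }
  stopifnot(is.data.frame(x), !is.null(widths))
  sum(ifelse(x$layout == "full",
             widths[x$row] * widths[x$col],
             widths[x$row] * (widths[x$row] - 1) / 2))
}
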