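# Model bundle on disk: model.json (version, config, target, decoders,
# memory metadata incl. per-class popcounts for integrity) plus one packed
# raw bit file per memory. Bit address for location (j, k) and class l
# (all zero-based) is ((j * w_col) + k) * n_classes + l, packed
# little-endian (bit 0 of each byte first), so model files are bit-exact
# across platforms.

MODEL_FORMAT_VERSION <- 1L

#' Save a fitted classifier to a directory
#'
#' @param model a fitted `"sbc_classifier"`.
#' @param dir directory to create/populate.
#' @return Invisibly, `dir`.
#' @seealso [read_sbc_model()]
#' @export
write_sbc_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  meta <- list(
    version = MODEL_FORMAT_VERSION,
    n_classes = model$n_classes,
    image_shape = model$image_shape,
    target = model$target$relative_mass,
    config = list(
      ad_specs = lapply(cfg$ad_specs, function(s) {
        list(n = s$n, w = s$w,
             locality_radius = if (is.null(s$locality_radius)) -1L else s$locality_radius,
             synapse_type = s$synapse_type, input_mode = s$input_mode)
      }),
      plan = cfg$sbc_plan,
      target_rate = cfg$target_rate, interval_t = cfg$interval_t,
      step = cfg$step, plasticity = cfg$plasticity, critical = cfg$critical,
      seed = cfg$seed
    ),
    ads = lapply(model$ads, function(a) {
      list(pixels = as.vector(a$pixels), weights = as.vector(a$weights),
           longevity = as.vector(a$longevity),
           threshold = a$threshold, centroid = a$centroid,
           w = a$w, n = a$n, synapse_type = a$synapse_type,
           input_mode = a$input_mode,
           locality_radius = if (is.null(a$locality_radius)) -1L else a$locality_radius)
    }),
    sbcs = lapply(model$sbcs, function(s) {
      list(row_ad_id = s$row_ad_id, col_ad_id = s$col_ad_id,
           w_row = s$w_row, w_col = s$w_col, layout = s$layout,
           popcounts = occupancy(s)$totals)
    })
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(model$sbcs)) {
    writeBin(pack_sbc_bits(model$sbcs[[i]]),
             file.path(dir, sprintf("sbc_%02d.bits", i)))
  }
  invisible(dir)
}

pack_sbc_bits <- function(sbc) {
  # bits[loc, l]: loc = (j-1)*w_col + k; address = (loc-1)*n_classes + (l-1)
  v <- as.logical(t(sbc$bits))
  pad <- (-length(v)) %% 8L
  if (pad > 0L) v <- c(v, rep(FALSE, pad))
  packBits(v, type = "raw")
}

unpack_sbc_bits <- function(raw_bytes, n_locs, n_classes) {
  v <- as.logical(rawToBits(raw_bytes))
  need <- n_locs * n_classes
  if (length(v) < need) stop("corrupt model: bit file too short", call. = FALSE)
  matrix(v[seq_len(need)], n_locs, n_classes, byrow = TRUE)
}

#' Load a classifier saved by [write_sbc_model()]
#'
#' Verifies the format version and the per-class popcounts recorded at
#' save time; a mismatch (e.g. a tampered or truncated bit file) raises a
#' corrupt-model error. The round trip is bit-exact: the loaded model
#' produces identical inference outputs.
#'
#' @param dir directory written by [write_sbc_model()].
#' @return An `"sbc_classifier"`.
#' @export
read_sbc_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  if (!identical(as.integer(meta$version), MODEL_FORMAT_VERSION)) {
    stop(sprintf("unsupported model format version %s (expected %d)",
                 meta$version, MODEL_FORMAT_VERSION), call. = FALSE)
  }
  shape <- as.integer(meta$image_shape)
  target <- structure(list(relative_mass = as.double(meta$target),
                           image_shape = shape), class = "sampling_target")
  restore_radius <- function(r) if (is.null(r) || r < 0) NULL else as.integer(r)
  ads <- lapply(meta$ads, function(a) {
    structure(list(
      pixels = matrix(as.integer(a$pixels), a$w, a$n),
      weights = matrix(as.integer(a$weights), a$w, a$n),
      longevity = matrix(as.integer(a$longevity), a$w, a$n),
      threshold = as.integer(a$threshold), centroid = as.integer(a$centroid),
      w = as.integer(a$w), n = as.integer(a$n),
      synapse_type = a$synapse_type, input_mode = a$input_mode,
      locality_radius = restore_radius(a$locality_radius),
      image_shape = shape
    ), class = "address_decoder")
  })
  cfgj <- meta$config
  specs <- lapply(cfgj$ad_specs, function(s) {
    ad_spec(s$n, s$w, restore_radius(s$locality_radius), s$synapse_type,
            s$input_mode)
  })
  plan <- data.frame(
    row = vapply(cfgj$plan, function(p) as.integer(p$row), integer(1)),
    col = vapply(cfgj$plan, function(p) as.integer(p$col), integer(1)),
    layout = vapply(cfgj$plan, function(p) p$layout, character(1)))
  config <- sbc_config(specs, plan, target_rate = cfgj$target_rate,
                       interval_t = cfgj$interval_t, step = cfgj$step,
                       plasticity = cfgj$plasticity, critical = cfgj$critical,
                       seed = cfgj$seed)
  sbcs <- lapply(seq_along(meta$sbcs), function(i) {
    s <- meta$sbcs[[i]]
    sbc <- create_sbc(s$row_ad_id, s$col_ad_id, s$w_row, s$w_col,
                      as.integer(meta$n_classes), s$layout)
    raw_bytes <- readBin(file.path(dir, sprintf("sbc_%02d.bits", i)), "raw",
                         n = ceiling(s$w_row * s$w_col * meta$n_classes / 8))
    sbc$bits <- unpack_sbc_bits(raw_bytes, s$w_row * s$w_col,
                                as.integer(meta$n_classes))
    if (!identical(occupancy(sbc)$totals, as.integer(s$popcounts))) {
      stop("corrupt model: memory popcount mismatch", call. = FALSE)
    }
    sbc
  })
  structure(list(config = config, target = target, ads = ads, sbcs = sbcs,
                 n_classes = as.integer(meta$n_classes), image_shape = shape),
            class = "sbc_classifier")
}
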