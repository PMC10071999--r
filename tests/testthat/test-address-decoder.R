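make_target <- function(seed = 1) {
  set <- synth_image_set(n_classes = 5, n_per_class = 20, seed = seed)
  list(target = sqrt_transform(accumulate_global_distribution(set)), set = set)
}

test_that("decoder construction obeys width, locality and multapse rules", {
  tg <- make_target()$target
  nr <- tg$image_shape[1]
  ad <- build_address_decoder(tg, w = 64, n = 6, "binary",
                              locality_radius = 2, seed = 3)
  expect_equal(dim(ad$pixels), c(64L, 6L))
  expect_true(all(apply(ad$pixels, 1, anyDuplicated) == 0))
  pr <- (ad$pixels - 1) %% nr + 1; pc <- (ad$pixels - 1) %/% nr + 1
  cr <- (ad$centroid - 1) %% nr + 1; cc <- (ad$centroid - 1) %/% nr + 1
  expect_true(all(abs(pr - cr) <= 2 & abs(pc - cc) <= 2))
  expect_true(all(ad$weights %in% c(-1L, 1L)))
  expect_true(all(ad$longevity == 16L))

  expect_identical(build_address_decoder(tg, 64, 6, "binary", 2, seed = 3), ad)

  mini <- build_address_decoder(tg, 1, 1, "binary", NULL, seed = 1)
  expect_equal(dim(mini$pixels), c(1L, 1L))

  ad8 <- build_address_decoder(tg, 16, 4, "int8", NULL, seed = 2)
  expect_true(all(ad8$weights != 0L & abs(ad8$weights) <= 127L))
})

test_that("element activation is the signed synapse dot product", {
  # all-zero raw image, centred to -127, binarised to -1 everywhere
  img <- center_pixels(matrix(0L, 4, 4))
  ade <- manual_ade(pixels = c(1, 2, 3), weights = c(1, 1, -1),
                    synapse_type = "binary", input_mode = "binary")
  expect_equal(ade_activation(ade, img), -1)

  ade8 <- manual_ade(pixels = c(1, 2), weights = c(3, -2), synapse_type = "int8")
  x <- matrix(0L, 1, 4); x[1, 1] <- 10L; x[1, 2] <- 5L
  expect_equal(ade_activation(ade8, x), 20)
  expect_equal(ade_activation(ade8, 2L * x), 40)  # linear in the input
})

test_that("firing uses the inclusive threshold inequality", {
  tg <- make_target()$target
  ad <- build_address_decoder(tg, 8, 4, "binary", NULL, seed = 5)
  img <- center_pixels(synth_image_set(2, 1, seed = 1)$images[, , 1])
  act <- vapply(1:8, function(j) ade_activation(ad_element(ad, j), img),
                numeric(1))
  ad$threshold <- as.integer(act)          # exactly equal -> fires
  expect_equal(decoder_firing_pattern(ad, img), 1:8)
  ad$threshold <- rep(.Machine$integer.max, 8L)
  expect_length(decoder_firing_pattern(ad, img), 0)
  ad$threshold <- rep(-.Machine$integer.max, 8L)
  expect_equal(decoder_firing_pattern(ad, img), 1:8)
  # monotonicity: raising one threshold never adds that element
  ad$threshold <- as.integer(act)
  ad$threshold[3] <- ad$threshold[3] + 1L
  expect_false(3 %in% decoder_firing_pattern(ad, img))
})

test_that("vectorised firing equals the per-element loop oracle", {
  tg <- make_target()$target
  fix <- make_target(seed = 2)
  for (type in c("binary", "int8")) for (mode in c("greyscale", "binary")) {
    ad <- build_address_decoder(tg, 32, 5, type, NULL, seed = 11,
                                input_mode = mode)
    ad$threshold <- as.integer(sample(-50:50, 32, replace = TRUE))
    for (i in 1:5) {
      raw <- fix$set$images[, , i]
      img <- center_pixels(raw)
      naive <- which(vapply(1:32, function(j) {
        ade <- ad_element(ad, j)
        ade_activation(ade, img) >= ade$threshold
      }, logical(1)))
      expect_equal(decoder_firing_pattern(ad, img), naive)
      # and the matrix path used in training agrees too
      ACT <- sbcmem:::ad_activation_matrix(ad, matrix(as.double(raw), 1))
      expect_equal(as.integer(ACT), sbcmem:::decoder_activations(ad, img))
    }
  }
})

test_that("threshold adaptation pins a constant stream near its activation", {
  # one repeated input: threshold converges to oscillate around the
  # single achievable activation value
  img <- synth_image_set(2, 1, seed = 3, jitter_px = 0,
                         intensity_noise_sd = 0)$images[, , 1]
  set <- image_set(array(img, c(dim(img), 1)), labels = 0L, n_classes = 2)
  tg <- sqrt_transform(accumulate_global_distribution(set))
  ad <- build_address_decoder(tg, 4, 5, "binary", NULL, seed = 2)
  a <- sbcmem:::decoder_activations(ad, center_pixels(img))
  adapted <- adapt_thresholds(ad, set, target_rate = 0.01, interval_t = 50,
                              step = 1L, n_presentations = 500, seed = 1)
  expect_true(all(abs(adapted$threshold - a) <= 2L))

  frozen <- adapt_thresholds(ad, set, target_rate = 0.01, interval_t = 50,
                             step = 0L, n_presentations = 500, seed = 1)
  expect_identical(frozen$threshold, ad$threshold)
})

test_that("homeostasis reaches within a factor two of the target rate", {
  fix <- synth_split(10, 50, 10, seed = 21)
  tg <- sqrt_transform(accumulate_global_distribution(fix$train))
  ad <- build_address_decoder(tg, 128, 6, "binary", 2, seed = 4)
  adapted <- adapt_thresholds(ad, fix$train, target_rate = 0.01,
                              interval_t = 250, n_presentations = 1500, seed = 8)
  rate <- mean(sbcmem:::decoder_firing_rates(adapted, fix$test))
  expect_gte(rate, 0.005)
  expect_lte(rate, 0.02)
})

test_that("plasticity rewards the largest and punishes the smallest contributor", {
  x <- matrix(0L, 1, 4)
  x[1, 1:3] <- c(5L, 3L, 9L)
  ade <- manual_ade(pixels = 1:3, weights = c(1, 1, 1), threshold = 0L)
  out <- plasticity_step(ade, x)
  expect_equal(out$longevity, c(16L, 15L, 17L))   # contributions 5, 3, 9

  # degenerate tie: argmin == argmax -> no change
  x2 <- matrix(0L, 1, 4); x2[1, 1:2] <- c(4L, 4L)
  tie <- plasticity_step(manual_ade(1:2, c(1, 1), 0L), x2)
  expect_equal(tie$longevity, c(16L, 16L))

  # longevity floors at zero
  low <- manual_ade(1:3, c(1, 1, 1), 0L, longevity = c(16L, 0L, 16L))
  expect_equal(plasticity_step(low, x)$longevity, c(16L, 0L, 17L))

  # calling on a non-firing element is a contract violation
  high <- manual_ade(1:3, c(1, 1, 1), threshold = 1000L)
  expect_error(plasticity_step(high, x), "contract violation")
})

test_that("batched plasticity equals sequential single-element steps", {
  tg <- make_target()$target
  raw <- synth_image_set(2, 1, seed = 6)$images[, , 1]
  img <- center_pixels(raw)
  ad <- build_address_decoder(tg, 16, 5, "binary", NULL, seed = 13)
  ad$threshold <- rep(-100L, 16L)   # everything fires
  fired <- decoder_firing_pattern(ad, img)
  batched <- sbcmem:::apply_plasticity(ad, fired, as.double(raw))
  seq_longevity <- ad$longevity
  for (j in fired) {
    ade <- ad_element(ad, j)
    ade$longevity <- seq_longevity[j, ]
    seq_longevity[j, ] <- plasticity_step(ade, img)$longevity
  }
  expect_equal(batched$longevity, seq_longevity)
})

test_that("weak synapses are replaced fresh, preserving all invariants", {
  tg <- make_target()$target
  ad <- build_address_decoder(tg, 8, 6, "binary", 3, seed = 17)
  expect_identical(replace_weak_synapses(ad, tg, critical = 1, seed = 1), ad)

  ad$longevity[3, 2] <- 0L
  out <- replace_weak_synapses(ad, tg, critical = 1, seed = 1)
  expect_false(out$pixels[3, 2] %in% ad$pixels[3, -2])
  expect_equal(out$longevity[3, 2], 16L)
  expect_equal(out$pixels[-3, ], ad$pixels[-3, ])
  expect_true(all(apply(out$pixels, 1, anyDuplicated) == 0))
  nr <- tg$image_shape[1]
  pr <- (out$pixels[3, 2] - 1) %% nr + 1; pc <- (out$pixels[3, 2] - 1) %/% nr + 1
  cr <- (out$centroid[3] - 1) %% nr + 1; cc <- (out$centroid[3] - 1) %/% nr + 1
  expect_true(abs(pr - cr) <= 3 && abs(pc - cc) <= 3)
})

test_that("unsupervised learning orchestrates without reading labels", {
  fix <- synth_split(5, 30, 10, seed = 31)
  tg <- sqrt_transform(accumulate_global_distribution(fix$train))
  ads <- list(build_address_decoder(tg, 64, 6, "binary", 2, seed = 1),
              build_address_decoder(tg, 64, 10, "binary", 3, seed = 2))

  expect_identical(unsupervised_learn(ads, fix$train, n_presentations = 0), ads)

  thr_only <- unsupervised_learn(ads, fix$train, target = tg,
                                 n_presentations = 3000, interval_t = 1000,
                                 plasticity = FALSE, replace = FALSE, seed = 3)
  expect_identical(thr_only[[1]]$pixels, ads[[1]]$pixels)
  expect_false(identical(thr_only[[1]]$threshold, ads[[1]]$threshold))

  full <- unsupervised_learn(ads, fix$train, target = tg,
                             n_presentations = 3000, interval_t = 1000, seed = 3)
  rates <- vapply(full, function(a) {
    mean(sbcmem:::decoder_firing_rates(a, fix$test))
  }, numeric(1))
  expect_true(all(rates >= 0.005 & rates <= 0.02))
  expect_true(all(vapply(full, function(a) {
    all(apply(a$pixels, 1, anyDuplicated) == 0)
  }, logical(1))))
})
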