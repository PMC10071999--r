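fake_bits <- function(idx, m = 100L) {
  structure(as.integer(idx), m = m, class = "coincidence_bits")
}

test_that("unrolled coincidence vectors match a brute-force double loop", {
  fix <- toy_model()
  m <- fix$model
  expect_equal(attr(unroll_bit_vector(m, fix$test$images[, , 1]), "m"),
               coincidence_space_size(m))
  for (i in 1:4) {
    img <- fix$test$images[, , i]
    v <- unroll_bit_vector(m, img)
    patterns <- lapply(m$ads, function(ad) {
      decoder_firing_pattern(ad, center_pixels(img))
    })
    # oracle: explicit loop over memories and active pairs
    plan <- m$config$sbc_plan
    expected <- integer(0); offset <- 0
    for (s in seq_along(m$sbcs)) {
      sbc <- m$sbcs[[s]]
      for (j in patterns[[plan$row[s]]]) for (k in patterns[[plan$col[s]]]) {
        if (sbc$layout == "half" && !(j < k)) next
        expected <- c(expected,
                      offset + sbcmem:::sbc_location_rank(sbc, j, k))
      }
      offset <- offset + sbcmem:::sbc_addressable(sbc)
    }
    expect_equal(as.integer(v), sort(expected))
    card <- sum(vapply(seq_along(m$sbcs), function(s) {
      length(patterns[[plan$row[s]]]) * length(patterns[[plan$col[s]]])
    }, numeric(1)))
    if (all(plan$layout == "full")) expect_equal(length(v), card)
  }

  # no element fires -> empty vector
  quiet <- m
  for (k in seq_along(quiet$ads)) {
    quiet$ads[[k]]$threshold <- rep(.Machine$integer.max, quiet$ads[[k]]$w)
  }
  expect_length(unroll_bit_vector(quiet, fix$test$images[, , 1]), 0)
})

test_that("the overlap kernel is the set-intersection cardinality", {
  a <- fake_bits(c(1, 5, 9)); b <- fake_bits(c(5, 9, 11))
  expect_equal(overlap_kernel(a, b), 2)
  expect_equal(overlap_kernel(a, a), length(a))
  expect_equal(overlap_kernel(a, fake_bits(c(2, 4))), 0)
  expect_error(overlap_kernel(a, fake_bits(1:3, m = 50L)), "different unrolled")
})

test_that("Gram matrices are symmetric and positive semi-definite", {
  set.seed(5)
  vs <- lapply(1:12, function(i) fake_bits(sort(sample.int(200, 40)), m = 200L))
  G <- gram_matrix(vs)
  expect_true(isSymmetric(G$K))
  expect_true(all(eigen(G$K, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-8 * max(G$K)))
  same <- gram_matrix(list(fake_bits(1:5), fake_bits(1:5), fake_bits(1:5)))
  expect_equal(same$K, matrix(5, 3, 3))
})

test_that("least-squares classification solves the hat system exactly", {
  # identity kernel: hat vectors equal the one-hot targets
  f <- lsc_fit(diag(4), labels = c(0, 1, 0, 1), n_classes = 2)
  expect_equal(f$H, cbind(c(1, 0, 1, 0), c(0, 1, 0, 1)))

  # 2x2 closed form: K = [[2,1],[1,2]], h_0 = (2/3, -1/3)
  K <- matrix(c(2, 1, 1, 2), 2)
  f2 <- lsc_fit(K, labels = c(0, 1), n_classes = 2)
  expect_equal(f2$H[, 1], c(2 / 3, -1 / 3))
  expect_equal(f2$H[, 2], c(-1 / 3, 2 / 3))

  expect_error(lsc_fit(matrix(1, 3, 3), labels = c(0, 1, 0), n_classes = 2),
               "singular")
})

test_that("block-structured Gram matrices give gating hat vectors", {
  # 10 classes x 10 cases; diagonal 3000, same-class 500, cross-class 50
  n <- 100; classes <- rep(0:9, each = 10)
  K <- matrix(50, n, n)
  for (cl in 0:9) K[classes == cl, classes == cl] <- 500
  diag(K) <- 3000
  f <- lsc_fit(K, classes, n_classes = 10)
  for (cl in 0:9) {
    own <- f$H[classes == cl, cl + 1]
    other <- f$H[classes != cl, cl + 1]
    expect_true(all(own > 0))
    expect_true(max(abs(other)) < min(own) / 2)
    # near-constant gating on the own class
    expect_lt(diff(range(own)) / mean(own), 1e-6)
  }
  # training rows classify perfectly
  pred <- apply(K, 1, function(ks) lsc_predict(ks, f)$class)
  expect_equal(pred, classes)
})

test_that("kernel predictions are linear with documented tie behaviour", {
  f <- lsc_fit(diag(3), labels = c(0, 1, 2), n_classes = 3)
  p <- lsc_predict(c(0.2, 0.9, 0.1), f)
  expect_equal(p$class, 1)
  expect_equal(p$indicators, c(0.2, 0.9, 0.1))
  expect_equal(lsc_predict(c(0, 0, 0), f)$indicators, rep(0, 3))
  expect_equal(lsc_predict(c(0, 0, 0), f)$class, 0)  # degenerate tie
  k1 <- c(1, 2, 3); k2 <- c(0.5, 0, 1)
  expect_equal(lsc_predict(k1 + k2, f)$indicators,
               lsc_predict(k1, f)$indicators + lsc_predict(k2, f)$indicators)
  expect_error(lsc_predict(c(1, 2), f), "does not match")
})

test_that("class-subset reports expose memorisation exactly", {
  fix <- toy_model()
  rep_ <- class_subset_report(fix$model, fix$train)
  M <- pairwise_intersections(fix$model$sbcs)
  expect_equal(rep_$intersections, M)
  expect_equal(rep_$cardinalities, diag(M))
  # every activated location of a training case was written for its class
  own <- rep_$cases[[paste0("overlap_", 0)]]
  for (i in seq_len(nrow(rep_$cases))) {
    lab <- rep_$cases$label[i]
    expect_equal(rep_$cases[[paste0("overlap_", lab)]][i], rep_$cases$card_o[i])
  }

  # a model trained on a single class has no cross-class intersections
  one <- synth_image_set(2, 5, seed = 91)
  onecls <- subset_images(one, which(one$labels == 0))
  onecls$n_classes <- 2L
  m1 <- sbc_classifier(onecls, preset_three_ad(w = 64, interval_t = 5, seed = 1))
  M1 <- pairwise_intersections(m1$sbcs)
  expect_true(all(M1[upper.tri(M1)] == 0))
})
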