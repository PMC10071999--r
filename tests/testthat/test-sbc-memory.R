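test_that("memory creation fixes capacity, layout and emptiness", {
  sbc <- create_sbc(1, 2, 8, 8, 10, "full")
  expect_equal(nrow(sbc$bits) * ncol(sbc$bits), 8 * 8 * 10)
  expect_equal(occupancy(sbc)$totals, rep(0L, 10))

  half <- create_sbc(1, 1, 4, 4, 3, "half")
  expect_equal(sbcmem:::sbc_addressable(half), choose(4, 2))
  expect_error(create_sbc(1, 2, 4, 4, 3, "half"), "same decoder")
})

test_that("coincidence writes set exactly the class bits of active pairs", {
  sbc <- create_sbc(1, 2, 8, 8, 10, "full")
  # elements 2 and 4 on rows, 3 on columns (1-based), class 7
  out <- write_coincidences(sbc, c(2L, 4L), 3L, 7L)
  expect_equal(sum(out$bits), 2)
  locs <- c((2 - 1) * 8 + 3, (4 - 1) * 8 + 3)
  expect_true(all(out$bits[locs, 8]))

  twice <- write_coincidences(out, c(2L, 4L), 3L, 7L)
  expect_identical(twice$bits, out$bits)

  expect_identical(write_coincidences(sbc, integer(0), 3L, 7L)$bits, sbc$bits)
  expect_error(write_coincidences(sbc, 1L, 1L, 10L), "label")
})

test_that("reads probe the same locations writes touch", {
  sbc <- create_sbc(1, 2, 16, 16, 4, "full")
  rowp <- c(2L, 5L, 9L); colp <- c(1L, 7L)
  expect_equal(read_counts(sbc, rowp, colp), rep(0L, 4))
  sbc <- write_coincidences(sbc, rowp, colp, 2L)
  counts <- read_counts(sbc, rowp, colp)
  expect_equal(counts, c(0L, 0L, length(rowp) * length(colp), 0L))
  expect_true(all(counts <= length(rowp) * length(colp)))

  half <- create_sbc(1, 1, 6, 6, 2, "half")
  patt <- c(1L, 3L, 4L)
  half <- write_coincidences(half, patt, patt, 0L)
  expect_equal(read_counts(half, patt, patt), c(choose(3, 2), 0L))
})

test_that("write/read equals a brute-force loop oracle on random patterns", {
  withr_seed <- 42
  set.seed(withr_seed)
  for (layout in c("full", "half")) {
    w <- 12L; nc <- 5L
    sbc <- create_sbc(1, 1, w, w, nc, layout)
    arr <- array(FALSE, dim = c(w, w, nc))
    for (rep_i in 1:10) {
      rp <- sort(sample.int(w, sample(0:5, 1)))
      cp <- sort(sample.int(w, sample(0:5, 1)))
      lb <- sample(0:(nc - 1L), 1)
      sbc <- write_coincidences(sbc, rp, cp, lb)
      arr <- oracle_write(arr, rp, cp, lb, layout)
    }
    for (rep_i in 1:10) {
      rp <- sort(sample.int(w, sample(0:6, 1)))
      cp <- sort(sample.int(w, sample(0:6, 1)))
      expect_equal(read_counts(sbc, rp, cp), oracle_counts(arr, rp, cp, layout))
    }
    expect_equal(occupancy(sbc)$totals,
                 as.integer(apply(arr, 3, sum)))
  }
})

test_that("prediction is argmax with documented tie-breaking", {
  expect_equal(as.integer(predict_from_counts(c(3, 9, 1))), 1L)
  expect_equal(as.integer(predict_from_counts(c(5, 5))), 0L)
  zero <- predict_from_counts(c(0, 0, 0))
  expect_equal(as.integer(zero), 0L)
  expect_true(attr(zero, "no_evidence"))
  expect_false(attr(predict_from_counts(c(1, 0)), "no_evidence"))
})

test_that("occupancy and pairwise intersections match popcount oracles", {
  sbc <- create_sbc(1, 2, 6, 6, 3, "full")
  one <- write_coincidences(sbc, 1L, 2L, 2L)
  expect_equal(occupancy(one)$totals, c(0L, 0L, 1L))
  expect_equal(occupancy(one)$fractions, c(0, 0, 1 / 36))

  # identical patterns written for two classes intersect fully
  both <- write_coincidences(one, 1L, 2L, 1L)
  M <- pairwise_intersections(list(both))
  expect_equal(diag(M), c(0L, 1L, 1L), ignore_attr = TRUE)
  expect_equal(M[2, 3], 1L)
  expect_equal(M[1, 2], 0L)

  # random memories vs explicit AND+popcount
  set.seed(7)
  s2 <- create_sbc(1, 2, 10, 10, 4, "full")
  for (i in 1:20) {
    s2 <- write_coincidences(s2, sample.int(10, 3), sample.int(10, 3),
                             sample(0:3, 1))
  }
  M2 <- pairwise_intersections(list(s2))
  for (a in 1:4) for (b in 1:4) {
    expect_equal(M2[a, b], sum(s2$bits[, a] & s2$bits[, b]))
  }
})

test_that("random forgetting clears exactly the requested number of bits", {
  set.seed(3)
  sbc <- create_sbc(1, 2, 10, 10, 4, "full")
  for (i in 1:10) {
    sbc <- write_coincidences(sbc, sample.int(10, 3), sample.int(10, 3),
                              sample(0:3, 1))
  }
  n0 <- sum(sbc$bits)
  expect_identical(random_forget(sbc, 0, seed = 1), sbc)
  f <- random_forget(sbc, 5, seed = 1)
  expect_equal(sum(f$bits), n0 - 5)
  expect_true(all(which(f$bits) %in% which(sbc$bits)))  # monotone clearing
  expect_identical(random_forget(sbc, 5, seed = 1), f)
  empty <- random_forget(sbc, n0, seed = 2)
  expect_equal(sum(empty$bits), 0)
  expect_error(random_forget(sbc, n0 + 1, seed = 1), "n_bits")
})
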