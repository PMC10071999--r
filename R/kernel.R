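# Kernel view of the coincidence mechanism. Every input activates a set
# of coincidence locations across all memories; unrolled into one long
# binary vector b of length m = sum of addressable locations, the logical
# AND of two such vectors is a dot product, so the set intersection
# |a n b| is a valid (Mercer) kernel -- the histogram/set-intersection
# kernel over the decoder-induced feature map. Least-squares
# classification on its Gram matrix is the explicit counterpart of the
# memory write/read mechanism.

# Rank of location (j, k) within one memory's addressable space, 1-based.
sbc_location_rank <- function(sbc, row_pattern, col_pattern) {
  if (length(row_pattern) == 0L || length(col_pattern) == 0L) return(integer(0))
  j <- rep(row_pattern, times = length(col_pattern))
  k <- rep(col_pattern, each = length(row_pattern))
  if (sbc$layout == "full") {
    (j - 1L) * sbc$w_col + k
  } else {
    keep <- j < k
    j <- j[keep]; k <- k[keep]
    w <- sbc$w_row
    # rank of (j, k), j < k, in row-major upper-triangle order
    (j - 1L) * w - j * (j - 1L) %/% 2L + (k - j)
  }
}

#' Unroll the coincidence bit vector of one image
#'
#' Maps every coincidence location the image activates -- across all
#' memories of the model -- to a fixed global index in the unrolled space
#' of length `m = coincidence_space_size(model)`. Only the decoders are
#' consulted; memory contents are not needed.
#'
#' @param model a fitted `"sbc_classifier"`.
#' @param image raw integer pixel matrix of the training shape.
#' @return Sorted integer vector of active indices (class
#'   `"coincidence_bits"`, attribute `m`). Its length equals the sum over
#'   memories of `|row active| * |col active|` (`j < k` pairs for half
#'   layout).
#' @export
unroll_bit_vector <- function(model, image) {
  patterns <- lapply(model$ads, function(ad) {
    decoder_firing_pattern(ad, center_pixels(image))
  })
  plan <- model$config$sbc_plan
  offset <- 0
  out <- vector("list", length(model$sbcs))
  for (s in seq_along(model$sbcs)) {
    sbc <- model$sbcs[[s]]
    r <- sbc_location_rank(sbc, patterns[[plan$row[s]]], patterns[[plan$col[s]]])
    out[[s]] <- offset + r
    offset <- offset + sbc_addressable(sbc)
  }
  structure(sort(unlist(out)), m = offset, class = "coincidence_bits")
}

#' Set-intersection (overlap) kernel
#'
#' `|a n b|`: the number of coincidence locations active in both vectors.
#' Self-similarity equals the vector's cardinality.
#'
#' @param a,b `"coincidence_bits"` vectors over the same unrolled space.
#' @return Nonnegative integer.
#' @export
overlap_kernel <- function(a, b) {
  if (!identical(attr(a, "m"), attr(b, "m"))) {
    stop_invalid("coincidence vectors come from different unrolled spaces")
  }
  length(intersect(as.integer(a), as.integer(b)))
}

#' Gram matrix of overlap-kernel values
#'
#' @param vectors list of `"coincidence_bits"` vectors.
#' @param ridge nonnegative ridge added to the diagonal at solve time;
#'   defaults to `1e-6 * trace(K) / n`, a tiny regularisation that keeps
#'   near-singular systems solvable.
#' @return Object of class `"gram_matrix"`: list with `K` (symmetric
#'   integer matrix, positive semi-definite by construction) and `ridge`.
#' @export
gram_matrix <- function(vectors, ridge = NULL) {
  n <- length(vectors)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    K[i, i] <- length(vectors[[i]])
    for (j in seq_len(i - 1L)) {
      K[i, j] <- K[j, i] <- overlap_kernel(vectors[[i]], vectors[[j]])
    }
  }
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(K)) / max(1L, n)
  if (ridge < 0) stop_invalid("ridge must be >= 0")
  structure(list(K = K, ridge = ridge), class = "gram_matrix")
}

#' Least-squares classification fit
#'
#' Solves `(K + ridge I) H = Y` for the one-hot class indicator targets
#' `Y`, giving one "hat" weight vector per class (the columns of `H`).
#'
#' @param K a `"gram_matrix"`, or a plain square matrix (then `ridge` is
#'   taken from the argument).
#' @param labels zero-based integer labels, one per training case.
#' @param n_classes number of classes.
#' @param ridge ridge used when `K` is a plain matrix (default 0).
#' @return Object of class `"lsc_fit"`: list with `H` (n x c), `ridge`
#'   and `n_classes`.
#' @export
lsc_fit <- function(K, labels, n_classes, ridge = 0) {
  if (inherits(K, "gram_matrix")) { ridge <- K$ridge; K <- K$K }
  n <- nrow(K)
  stopifnot(ncol(K) == n, length(labels) == n)
  Y <- matrix(0, n, n_classes)
  Y[cbind(seq_len(n), as.integer(labels) + 1L)] <- 1
  H <- tryCatch(
    solve(K + diag(ridge, n), Y),
    error = function(e) {
      stop("singular kernel system: increase the ridge regularisation",
           call. = FALSE)
    }
  )
  structure(list(H = H, ridge = ridge, n_classes = n_classes),
            class = "lsc_fit")
}

#' Least-squares classification prediction
#'
#' Class indicator `i` is the dot product of the new case's kernel vector
#' `k*` (its similarity to every training case) with the class's hat
#' vector; the largest indicator gives the class, ties to the lowest
#' index.
#'
#' @param k_star numeric vector of kernel values between the new case and
#'   the `n` training cases.
#' @param fit an `"lsc_fit"`.
#' @return List with `indicators` (length-c numeric) and `class`
#'   (zero-based integer).
#' @export
lsc_predict <- function(k_star, fit) {
  stopifnot(inherits(fit, "lsc_fit"))
  if (length(k_star) != nrow(fit$H)) {
    stop_invalid("k_star length %d does not match %d training cases",
                 length(k_star), nrow(fit$H))
  }
  ind <- drop(crossprod(fit$H, as.numeric(k_star)))
  list(indicators = ind, class = which.max(ind) - 1L)
}

#' Class-subset cardinality and intersection diagnostics
#'
#' Summarises the written memories as class subsets of the unrolled
#' coincidence space: per-class cardinalities (diagonal), pairwise
#' intersection cardinalities (off-diagonal), and for every test image
#' the cardinality of its active-bit vector `o*` together with its
#' overlap with each class subset (which are exactly the inference bit
#' counts). For a training case probed against its own class the overlap
#' equals `card(o*)`: every activated location was written.
#'
#' @param model a fitted `"sbc_classifier"`.
#' @param test_images an [image_set()] (labels, when present, are echoed
#'   in the per-case table).
#' @return List with `cardinalities`, `intersections` (c x c matrix) and
#'   `cases` (data frame: `card_o`, `label`, one overlap column per
#'   class).
#' @export
class_subset_report <- function(model, test_images) {
  inter <- pairwise_intersections(model$sbcs)
  res <- infer(model, test_images)
  card_o <- vapply(seq_len(n_images(test_images)), function(i) {
    length(unroll_bit_vector(model, test_images$images[, , i]))
  }, numeric(1))
  overlaps <- res$counts
  colnames(overlaps) <- paste0("overlap_", 0:(model$n_classes - 1L))
  cases <- data.frame(card_o = card_o,
                      label = if (length(test_images$labels)) test_images$labels else NA_integer_,
                      overlaps)
  list(cardinalities = diag(inter), intersections = inter, cases = cases)
}
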