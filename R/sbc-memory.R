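# Sparse binary coincidence (SBC) memories: 2D bit stores indexed by pairs
# of firing element indices from a row decoder and a column decoder, with
# one bit per class at each location. In-memory representation: a logical
# matrix `bits` of (w_row * w_col) linearised locations x n_classes, with
# location (j, k) at row (j - 1) * w_col + k. Half-size memories (row and
# column decoder identical) address only the strict upper triangle j < k.

#' Create an empty SBC memory
#'
#' @param row_ad_id,col_ad_id identifiers (indices) of the row and column
#'   address decoders. Half layout requires them to be equal.
#' @param w_row,w_col decoder widths.
#' @param n_classes number of class bits per location.
#' @param layout `"full"` (all `w_row x w_col` locations) or `"half"`
#'   (within-decoder memory storing only the strict upper triangle
#'   `j < k` of unique coincidences; the self-coincidence diagonal carries
#'   no pairwise information and is excluded).
#' @return An object of class `"sbc_memory"` with all bits cleared.
#' @export
create_sbc <- function(row_ad_id, col_ad_id, w_row, w_col, n_classes,
                       layout = c("full", "half")) {
  layout <- match.arg(layout)
  if (layout == "half" && row_ad_id != col_ad_id) {
    stop_invalid("half layout requires the same decoder on rows and columns")
  }
  if (layout == "half" && w_row != w_col) stop_invalid("half layout requires w_row == w_col")
  w_row <- as.integer(w_row); w_col <- as.integer(w_col)
  n_classes <- as.integer(n_classes)
  structure(
    list(row_ad_id = row_ad_id, col_ad_id = col_ad_id,
         w_row = w_row, w_col = w_col, n_classes = n_classes, layout = layout,
         bits = matrix(FALSE, w_row * w_col, n_classes)),
    class = "sbc_memory"
  )
}

#' @export
print.sbc_memory <- function(x, ...) {
  cat(sprintf("<sbc_memory> %s, %d x %d (decoders %s x %s), %d classes, %d bits set\n",
              x$layout, x$w_row, x$w_col, x$row_ad_id, x$col_ad_id,
              x$n_classes, sum(x$bits)))
  invisible(x)
}

# Number of addressable coincidence locations.
sbc_addressable <- function(sbc) {
  if (sbc$layout == "full") sbc$w_row * sbc$w_col
  else sbc$w_row * (sbc$w_row - 1L) / 2L
}

# Linearised location indices probed by a (row_pattern, col_pattern) pair.
# Reads and writes share this function, so the probed set is identical for
# both operations by construction.
sbc_locations <- function(sbc, row_pattern, col_pattern) {
  if (length(row_pattern) == 0L || length(col_pattern) == 0L) return(integer(0))
  if (max(row_pattern) > sbc$w_row || max(col_pattern) > sbc$w_col ||
      min(row_pattern) < 1L || min(col_pattern) < 1L) {
    stop_invalid("firing pattern index out of decoder range")
  }
  j <- rep(row_pattern, times = length(col_pattern))
  k <- rep(col_pattern, each = length(row_pattern))
  if (sbc$layout == "half") {
    keep <- j < k
    j <- j[keep]; k <- k[keep]
  }
  (j - 1L) * sbc$w_col + k
}

#' Write the coincidences of one labelled example
#'
#' Sets the class bit `label` at every coincidence location `(j, k)` with
#' `j` active in the row pattern and `k` active in the column pattern
#' (restricted to `j < k` for half layout). Setting an already-set bit
#' changes nothing, so writes are idempotent and order-independent.
#'
#' @param sbc an [create_sbc()] memory.
#' @param row_pattern,col_pattern integer vectors of firing element
#'   indices (1-based), e.g. from [decoder_firing_pattern()].
#' @param label zero-based class id.
#' @return The updated memory.
#' @export
write_coincidences <- function(sbc, row_pattern, col_pattern, label) {
  label <- as.integer(label)
  if (label < 0L || label >= sbc$n_classes) stop_invalid("label out of range")
  locs <- sbc_locations(sbc, row_pattern, col_pattern)
  if (length(locs) > 0L) sbc$bits[locs, label + 1L] <- TRUE
  sbc
}

#' Count set class bits over the probed coincidences
#'
#' Probes exactly the locations [write_coincidences()] would touch for the
#' same patterns and returns, per class, the number of probed locations
#' whose class bit is set.
#'
#' @inheritParams write_coincidences
#' @return Integer vector of length `n_classes`.
#' @export
read_counts <- function(sbc, row_pattern, col_pattern) {
  locs <- sbc_locations(sbc, row_pattern, col_pattern)
  if (length(locs) == 0L) return(integer(sbc$n_classes))
  as.integer(colSums(sbc$bits[locs, , drop = FALSE]))
}

#' Predict a class from accumulated bit counts
#'
#' The highest per-class sum of set bits across all memories indicates the
#' inferred class; ties are broken deterministically by the lowest class
#' index. An all-zero count vector carries no evidence: class 0 is
#' returned with attribute `no_evidence = TRUE`.
#'
#' @param counts numeric/integer vector of per-class bit counts.
#' @return Zero-based class id (integer) with attribute `no_evidence`.
#' @export
predict_from_counts <- function(counts) {
  if (length(counts) < 1L) stop_invalid("need at least one class")
  structure(which.max(counts) - 1L, no_evidence = all(counts == 0))
}

#' Per-class occupancy of an SBC memory
#'
#' @param sbc an SBC memory.
#' @return List with `totals` (per-class popcount of set bits) and
#'   `fractions` (totals divided by the addressable location count).
#' @export
occupancy <- function(sbc) {
  totals <- as.integer(colSums(sbc$bits))
  list(totals = totals, fractions = totals / sbc_addressable(sbc))
}

#' Pairwise class-subset intersection cardinalities
#'
#' For every class pair `(a, b)`, counts the memory locations where both
#' class bits are set, summed over the supplied memories. The diagonal
#' equals the per-class occupancy totals.
#'
#' @param sbcs a list of SBC memories sharing one `n_classes`.
#' @return Symmetric `n_classes x n_classes` integer matrix.
#' @export
pairwise_intersections <- function(sbcs) {
  if (inherits(sbcs, "sbc_memory")) sbcs <- list(sbcs)
  c0 <- sbcs[[1L]]$n_classes
  M <- matrix(0, c0, c0)
  for (sbc in sbcs) {
    stopifnot(sbc$n_classes == c0)
    B <- sbc$bits * 1L
    M <- M + crossprod(B)
  }
  storage.mode(M) <- "integer"
  dimnames(M) <- list(0:(c0 - 1L), 0:(c0 - 1L))
  M
}

#' Randomly forget set bits
#'
#' Clears exactly `n_bits` uniformly chosen currently-set bits; the
#' mechanism behind occupancy-stabilised continuous learning, where the
#' bits added by new examples are balanced by random removal.
#'
#' @param sbc an SBC memory.
#' @param n_bits number of set bits to clear (at most the current
#'   popcount).
#' @param seed integer seed.
#' @return The updated memory.
#' @export
random_forget <- function(sbc, n_bits, seed = 1) {
  n_bits <- as.integer(n_bits)
  set_idx <- which(sbc$bits)
  if (n_bits < 0L || n_bits > length(set_idx)) {
    stop_invalid("n_bits must lie in [0, number of set bits]")
  }
  if (n_bits == 0L) return(sbc)
  with_seed(seed, function() {
    drop <- sample(set_idx, n_bits)
    sbc$bits[drop] <- FALSE
    sbc
  })
}
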