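#' @export
print.sbc_classifier <- function(x, ...) {
  specs <- x$config$ad_specs
  cat("Sparse binary coincidence memory classifier\n")
  cat(sprintf("  decoders: %d (widths n = %s; w = %s; %s synapses)\n",
              length(x$ads),
              paste(vapply(specs, function(s) s$n, integer(1)), collapse = ", "),
              paste(vapply(specs, function(s) s$w, integer(1)), collapse = ", "),
              specs[[1L]]$synapse_type))
  plan <- x$config$sbc_plan
  cat(sprintf("  memories: %d (%d full, %d half); classes: %d\n",
              nrow(plan), sum(plan$layout == "full"), sum(plan$layout == "half"),
              x$n_classes))
  occ <- vapply(x$sbcs, function(s) sum(s$bits), numeric(1))
  addr <- vapply(x$sbcs, sbc_addressable, numeric(1)) * x$n_classes
  cat(sprintf("  occupancy: %s bits set of %s (%.2f%%)\n",
              format(sum(occ), big.mark = ","), format(sum(addr), big.mark = ","),
              100 * sum(occ) / sum(addr)))
  invisible(x)
}

#' Summary of a fitted SBC classifier
#'
#' Reports the per-memory, per-class occupancy (fraction of addressable
#' coincidence locations whose class bit is set) and the mean firing
#' thresholds per decoder.
#'
#' @param object a fitted `"sbc_classifier"`.
#' @param ... unused.
#' @return A list of class `"summary.sbc_classifier"` with elements
#'   `occupancy` (memories x classes matrix of fractions) and
#'   `thresholds` (per-decoder summary).
#' @export
summary.sbc_classifier <- function(object, ...) {
  occ <- t(vapply(object$sbcs, function(s) occupancy(s)$fractions,
                  numeric(object$n_classes)))
  plan <- object$config$sbc_plan
  rownames(occ) <- sprintf("%s(%d,%d)", plan$layout, plan$row, plan$col)
  colnames(occ) <- 0:(object$n_classes - 1L)
  thr <- t(vapply(object$ads, function(a) {
    c(min = min(a$threshold), mean = mean(a$threshold), max = max(a$threshold))
  }, numeric(3)))
  structure(list(occupancy = occ, thresholds = thr,
                 space = coincidence_space_size(object)),
            class = "summary.sbc_classifier")
}

#' @export
print.summary.sbc_classifier <- function(x, ...) {
  cat(sprintf("Coincidence space: %s locations\n", format(x$space, big.mark = ",")))
  cat("Per-memory, per-class occupancy fractions:\n")
  print(round(x$occupancy, 4))
  cat("Decoder thresholds (min / mean / max):\n")
  print(round(x$thresholds, 2))
  invisible(x)
}

#' Plot per-class memory occupancy
#'
#' Barplot of the fraction of addressable coincidence locations set per
#' class, summed over all memories. Classes with systematically fewer set
#' bits tend to be those whose examples are most self-similar.
#'
#' @param x a fitted `"sbc_classifier"`.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the plotted per-class fractions.
#' @export
plot.sbc_classifier <- function(x, ...) {
  totals <- Reduce(`+`, lapply(x$sbcs, function(s) occupancy(s)$totals))
  addr <- sum(vapply(x$sbcs, sbc_addressable, numeric(1)))
  frac <- totals / addr
  graphics::barplot(frac, names.arg = 0:(x$n_classes - 1L),
                    xlab = "class", ylab = "occupancy fraction", ...)
  invisible(frac)
}
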