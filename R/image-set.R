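#' Labelled image sets
#'
#' The unit of data consumed by training, inference and noise injection: a
#' stack of 8-bit greyscale raster images plus an integer class label per
#' image. Labels are zero-based, in `[0, n_classes)`, following the MNIST
#' convention.
#'
#' @param images a `rows x cols x n` integer array of pixel values in
#'   `[0, 255]`, or a list of equally-sized integer matrices.
#' @param labels integer vector of class labels, one per image, zero-based.
#' @param n_classes total number of classes. Defaults to `max(labels) + 1`
#'   (10 when the set is empty).
#'
#' @return An object of class `"image_set"`: a list with elements `images`
#'   (3D integer array), `labels`, `n_classes` and `image_shape`.
#' @export
#' @examples
#' img <- matrix(0L, 4, 4)
#' s <- image_set(array(img, c(4, 4, 1)), labels = 0L, n_classes = 2)
#' s$image_shape
image_set <- function(images, labels, n_classes = NULL) {
  if (is.list(images)) {
    if (length(images) == 0L) {
      images <- array(integer(0), dim = c(0L, 0L, 0L))
    } else {
      shp <- dim(images[[1L]])
      if (is.null(shp) || length(shp) != 2L) stop_invalid("images must be 2D matrices")
      if (!all(vapply(images, function(m) identical(dim(m), shp), logical(1)))) {
        stop_invalid("all images must share one shape")
      }
      images <- array(unlist(images, use.names = FALSE), dim = c(shp, length(images)))
    }
  }
  if (!is.array(images) || length(dim(images)) != 3L) {
    stop_invalid("images must be a rows x cols x n array or a list of matrices")
  }
  storage.mode(images) <- "integer"
  n <- dim(images)[3L]
  labels <- as.integer(labels)
  if (length(labels) != n) stop_invalid("%d images but %d labels", n, length(labels))
  if (n > 0L && (anyNA(images) || min(images) < 0L || max(images) > 255L)) {
    stop_invalid("pixel values must lie in [0, 255]")
  }
  if (is.null(n_classes)) n_classes <- if (n > 0L) max(labels) + 1L else 10L
  n_classes <- as.integer(n_classes)
  if (n > 0L && (anyNA(labels) || min(labels) < 0L || max(labels) >= n_classes)) {
    stop_invalid("labels must lie in [0, n_classes)")
  }
  structure(
    list(images = images, labels = labels, n_classes = n_classes,
         image_shape = dim(images)[1:2]),
    class = "image_set"
  )
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("<image_set> %d images of %d x %d, %d classes\n",
              length(x$labels), x$image_shape[1L], x$image_shape[2L], x$n_classes))
  if (length(x$labels) > 0L) {
    tab <- table(factor(x$labels, levels = 0:(x$n_classes - 1L)))
    cat("  per-class counts:", paste(as.integer(tab), collapse = " "), "\n")
  }
  invisible(x)
}

# n x (rows*cols) matrix of raw pixel values, one row per image.
# Pixel j of the flattened vector is (col-1)*rows + row (column-major),
# the same order used by the pixel-mass accumulator and the samplers.
set_matrix <- function(set) {
  d <- dim(set$images)
  t(matrix(as.double(set$images), d[1L] * d[2L], d[3L]))
}

n_images <- function(set) dim(set$images)[3L]

subset_images <- function(set, idx) {
  image_set(set$images[, , idx, drop = FALSE], set$labels[idx], set$n_classes)
}
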