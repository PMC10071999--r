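#' Read an IDX image/label file pair
#'
#' Reads the MNIST-dialect IDX container: a big-endian magic word
#' (`0x00000803` for unsigned-byte rank-3 image tensors, `0x00000801` for
#' label vectors), big-endian 32-bit dimension sizes, then the raw
#' unsigned-byte payload. Pixel values are preserved exactly.
#'
#' @param image_path path to the images file.
#' @param label_path path to the labels file.
#' @return An [image_set()].
#' @export
read_idx <- function(image_path, label_path) {
  imgs <- read_idx_images(image_path)
  labels <- read_idx_labels(label_path)
  if (dim(imgs)[3L] != length(labels)) {
    stop(sprintf("format error: image count %d does not match label count %d",
                 dim(imgs)[3L], length(labels)), call. = FALSE)
  }
  image_set(imgs, labels)
}

read_idx_images <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (length(magic) != 1L || magic != 0x00000803L) {
    stop("format error: images magic number is not 0x00000803", call. = FALSE)
  }
  dims <- readBin(con, "integer", 3L, size = 4L, endian = "big")
  if (length(dims) != 3L || any(dims < 0L)) {
    stop("format error: truncated or invalid image dimension header", call. = FALSE)
  }
  n <- dims[1L]; rows <- dims[2L]; cols <- dims[3L]
  payload <- readBin(con, "raw", n * rows * cols)
  if (length(payload) != n * rows * cols) {
    stop("format error: truncated image payload", call. = FALSE)
  }
  # IDX stores each image row-major; fill cols-then-rows and permute back
  arr <- array(as.integer(payload), dim = c(cols, rows, max(n, 0L)))
  aperm(arr, c(2L, 1L, 3L))
}

read_idx_labels <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (length(magic) != 1L || magic != 0x00000801L) {
    stop("format error: labels magic number is not 0x00000801", call. = FALSE)
  }
  n <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (length(n) != 1L || n < 0L) {
    stop("format error: truncated label count header", call. = FALSE)
  }
  payload <- readBin(con, "raw", n)
  if (length(payload) != n) stop("format error: truncated label payload", call. = FALSE)
  as.integer(payload)
}

#' Write an image set as an IDX file pair
#'
#' Emits the standard big-endian IDX layout so that synthetic and real
#' data travel through identical files: images as magic `0x00000803` with
#' dimensions `(n, rows, cols)` and row-major pixel bytes, labels as magic
#' `0x00000801` with dimension `(n)`.
#'
#' @param set an [image_set()].
#' @inheritParams read_idx
#' @return Invisibly, `NULL`. Errors if a path is unwritable.
#' @export
write_idx <- function(set, image_path, label_path) {
  stopifnot(inherits(set, "image_set"))
  n <- n_images(set)
  rows <- set$image_shape[1L]; cols <- set$image_shape[2L]
  con <- tryCatch(file(image_path, "wb"),
                  error = function(e) stop("io error: cannot open ", image_path, call. = FALSE))
  writeBin(c(0x00000803L, n, rows, cols), con, size = 4L, endian = "big")
  if (n > 0L) {
    writeBin(as.raw(as.vector(aperm(set$images, c(2L, 1L, 3L)))), con)
  }
  close(con)
  con <- tryCatch(file(label_path, "wb"),
                  error = function(e) stop("io error: cannot open ", label_path, call. = FALSE))
  writeBin(c(0x00000801L, n), con, size = 4L, endian = "big")
  if (n > 0L) writeBin(as.raw(set$labels), con)
  close(con)
  invisible(NULL)
}
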