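#' Gel image stack
#'
#' An ordered collection of equally-sized 2D grayscale gel images with
#' per-sample identifiers and a per-pixel-per-image validity mask. Intensities
#' are stored as floats in their original camera units (8-bit images in
#' 0..255, 16-bit in 0..65535 — no rescaling at load). The validity mask marks
#' pixels that carry observed data; alignment marks resampled pixels that fall
#' outside the source image footprint as invalid so that they are treated as
#' missing downstream rather than as zeros.
#'
#' @param images list of numeric matrices, all with identical dimensions, or a
#'   3D array `H x W x n`.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   image.
#' @param valid optional logical array `H x W x n`; defaults to all-`TRUE`.
#' @return An object of class `gel_stack`: a list with elements `data`
#'   (numeric `H x W x n` array), `valid` (logical array of the same shape)
#'   and `sample_ids`.
#' @examples
#' s <- gel_stack(list(matrix(1:4, 2), matrix(5:8, 2)), c("a", "b"))
#' dim(s)
#' @export
gel_stack <- function(images, sample_ids, valid = NULL) {
  if (is.list(images)) {
    dims <- lapply(images, dim)
    if (length(images) == 0) gc_stop("empty image list", "gelcorr_stack_error")
    d1 <- dims[[1]]
    for (i in seq_along(dims)) {
      if (is.null(dims[[i]]) || length(dims[[i]]) != 2L) {
        gc_stop(sprintf("image %d is not a 2D matrix", i), "gelcorr_stack_error")
      }
      if (!identical(dims[[i]], d1)) {
        gc_stop(sprintf(
          "image dimension mismatch: image 1 is %dx%d but image %d is %dx%d",
          d1[1], d1[2], i, dims[[i]][1], dims[[i]][2]
        ), "gelcorr_dim_error")
      }
    }
    data <- array(unlist(images, use.names = FALSE), dim = c(d1, length(images)))
  } else if (is.array(images) && length(dim(images)) == 3L) {
    data <- images
  } else {
    gc_stop("images must be a list of matrices or a 3D array", "gelcorr_stack_error")
  }
  n <- dim(data)[3]
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) {
    gc_stop("length(sample_ids) must equal the number of images", "gelcorr_stack_error")
  }
  if (anyDuplicated(sample_ids)) {
    gc_stop("sample_ids must be unique", "gelcorr_id_error")
  }
  if (n < 2L) gc_stop("a gel stack needs at least 2 images", "gelcorr_stack_error")
  if (is.null(valid)) {
    valid <- array(TRUE, dim = dim(data))
  }
  if (!identical(dim(valid), dim(data))) {
    gc_stop("valid mask must have the same shape as the image stack", "gelcorr_stack_error")
  }
  structure(
    list(data = data, valid = valid, sample_ids = sample_ids),
    class = "gel_stack"
  )
}

#' @export
dim.gel_stack <- function(x) dim(x$data)

#' Number of samples (images) in a gel stack
#' @param stack a [gel_stack].
#' @return integer count of images.
#' @export
n_samples <- function(stack) dim(stack$data)[3]

#' Extract one image from a gel stack
#' @param stack a [gel_stack].
#' @param i image index or sample id.
#' @return numeric matrix.
#' @export
stack_image <- function(stack, i) {
  if (is.character(i)) i <- match(i, stack$sample_ids)
  stack$data[, , i]
}

#' @export
print.gel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<gel_stack> %d images of %d x %d pixels (%.1f%% pixels valid)\n",
    d[3], d[1], d[2], 100 * mean(x$valid)
  ))
  cat("samples:", paste(x$sample_ids, collapse = ", "), "\n")
  invisible(x)
}
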