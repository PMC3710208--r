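#' Per-image intensity normalization
#'
#' Even with controlled protein amounts and imaging, gel-to-gel intensity
#' variability remains (manual membrane handling, exposure differences).
#' Three per-image schemes are offered, each computed over that image's
#' *valid* pixels only (post-alignment masks; off-canvas pixels would corrupt
#' the statistics):
#'
#' * `mean`: divide by the image's mean pixel value;
#' * `median`: divide by the image's median pixel value — the recommended
#'   default, robust to the strong spot intensities in the upper tail;
#' * `zscore`: subtract the image mean and divide by the population standard
#'   deviation (divisor `N`);
#' * `none`: pass through unchanged.
#'
#' Masked-out pixels propagate unchanged and remain masked. Mean and median
#' normalization make the output invariant to per-image global intensity
#' scaling, which is exactly the nuisance they exist to remove.
#'
#' @param image numeric matrix.
#' @param mask logical matrix of valid pixels (default all valid).
#' @param scheme one of `"none"`, `"mean"`, `"median"`, `"zscore"`.
#' @return normalized numeric matrix.
#' @examples
#' normalize_image(matrix(c(2, 4, 6, 8), 2), scheme = "mean")  # mu = 5
#' @export
normalize_image <- function(image, mask = NULL,
                            scheme = c("median", "mean", "zscore", "none")) {
  scheme <- match.arg(scheme)
  if (scheme == "none") return(image)
  if (is.null(mask)) mask <- !is.na(image) & array(TRUE, dim = dim(image))
  v <- image[mask]
  if (length(v) < 1) gc_stop("no valid pixels to normalize", "gelcorr_degenerate_error")
  out <- image
  if (scheme == "mean" || scheme == "median") {
    s <- if (scheme == "mean") mean(v) else median(v)
    if (!is.finite(s) || s == 0) {
      gc_stop(sprintf("degenerate image: %s scale is zero", scheme),
              "gelcorr_degenerate_error")
    }
    out[mask] <- v / s
  } else {
    mu <- mean(v)
    sigma <- sqrt(mean((v - mu)^2))   # population sd, divisor N
    if (!is.finite(sigma) || sigma == 0) {
      gc_stop("degenerate image: zero standard deviation for z-score",
              "gelcorr_degenerate_error")
    }
    out[mask] <- (v - mu) / sigma
  }
  out
}

#' Normalize every image of a gel stack
#'
#' Applies [normalize_image()] independently to each image, using each
#' image's own validity mask; masks are preserved. Per-image degenerate
#' images (zero scale or zero spread) are reported together with their
#' sample ids.
#'
#' @param stack a [gel_stack].
#' @param scheme normalization scheme, see [normalize_image()].
#' @return the normalized [gel_stack].
#' @export
normalize_stack <- function(stack, scheme = c("median", "mean", "zscore", "none")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(stack, "gel_stack"))
  if (scheme == "none") return(stack)
  out <- stack
  failures <- character(0)
  for (i in seq_len(n_samples(stack))) {
    res <- tryCatch(
      normalize_image(stack$data[, , i], stack$valid[, , i], scheme),
      gelcorr_degenerate_error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s (%s)", stack$sample_ids[i], conditionMessage(res)))
    } else {
      out$data[, , i] <- res
    }
  }
  if (length(failures)) {
    gc_stop(paste0("normalization failed for sample(s): ",
                   paste(failures, collapse = "; ")),
            "gelcorr_degenerate_error")
  }
  out
}
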