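#' Similarity transform (rotation, uniform scale, translation)
#'
#' The 4-parameter transform family used for gel alignment. Gel images shift,
#' rotate and shrink/stretch slightly between runs, but the method
#' deliberately avoids warping (non-rigid registration), so alignment is
#' restricted to exactly this family.
#'
#' Composition convention (fixed; all parameter files use it):
#' `output(p) = s * R(theta) %*% (p - c) + c + t`, where `p = (x, y)` is a
#' 0-based pixel coordinate with `x` = column (rightwards) and `y` = row
#' (downwards), `c = ((W-1)/2, (H-1)/2)` is the image center,
#' `R(theta)` rotates by `rotation_deg` degrees counter-clockwise as
#' displayed (origin top-left, +y down), scaling is applied with the
#' rotation about the center, and the translation `t = (tx, ty)` in pixels
#' is applied last. The identity is `(0, 1, 0, 0)`.
#'
#' @param rotation_deg rotation in degrees, counter-clockwise on screen.
#' @param scale uniform scale factor, must be `> 0`.
#' @param tx,ty translation in pixels (+x right, +y down).
#' @return object of class `similarity_transform`.
#' @examples
#' identity_transform()
#' invert(similarity_transform(0, 2, 0, 0))  # pure scale 2 -> scale 0.5
#' @export
similarity_transform <- function(rotation_deg = 0, scale = 1, tx = 0, ty = 0) {
  p <- c(rotation_deg, scale, tx, ty)
  if (length(p) != 4 || !all(is.finite(p))) {
    gc_stop("transform parameters must be four finite numbers", "gelcorr_param_error")
  }
  if (scale <= 0) gc_stop("scale must be > 0", "gelcorr_param_error")
  structure(list(rotation_deg = rotation_deg, scale = scale, tx = tx, ty = ty),
            class = "similarity_transform")
}

#' @rdname similarity_transform
#' @export
identity_transform <- function() similarity_transform(0, 1, 0, 0)

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> rot=%g deg, scale=%g, t=(%g, %g) px\n",
              x$rotation_deg, x$scale, x$tx, x$ty))
  invisible(x)
}

## In complex form (z = x + i*y, +y down) the linear part is multiplication
## by a = scale * exp(-i * theta): display-CCW rotation corresponds to e^(-i theta)
## because the y axis points down.
t_complex <- function(t) {
  th <- t$rotation_deg * pi / 180
  list(a = t$scale * exp(-1i * th), b = complex(real = t$tx, imaginary = t$ty))
}

#' Invert a similarity transform
#'
#' @param t a [similarity_transform].
#' @return the [similarity_transform] `t_inv` with
#'   `apply_transform(apply_transform(img, t), t_inv)` restoring `img` on the
#'   jointly valid region (up to interpolation error).
#' @export
invert <- function(t) {
  stopifnot(inherits(t, "similarity_transform"))
  z <- t_complex(t)
  ti <- -z$b / z$a
  similarity_transform(-t$rotation_deg, 1 / t$scale, Re(ti), Im(ti))
}

#' Compose two similarity transforms
#'
#' `compose(t2, t1)` is the transform equivalent to applying `t1` first and
#' then `t2` (function-composition order, both about the same image center).
#'
#' @param t2,t1 [similarity_transform]s.
#' @return the composed [similarity_transform].
#' @export
compose <- function(t2, t1) {
  stopifnot(inherits(t2, "similarity_transform"), inherits(t1, "similarity_transform"))
  z2 <- t_complex(t2)
  tn <- z2$a * complex(real = t1$tx, imaginary = t1$ty) + z2$b
  similarity_transform(t1$rotation_deg + t2$rotation_deg, t1$scale * t2$scale,
                       Re(tn), Im(tn))
}

#' Apply a similarity transform to an image
#'
#' Resamples by inverse mapping: for every output pixel the source coordinate
#' is computed with the inverse transform and the source image sampled there
#' by nearest-neighbor or bilinear interpolation. Output pixels whose source
#' coordinate falls outside the source footprint `[0, W-1] x [0, H-1]` are
#' set to 0 and flagged invalid in the returned mask: they are missing data,
#' not zeros — feeding border zeros into the statistics would fabricate
#' spurious (anti-)correlations.
#'
#' @param image numeric matrix.
#' @param t a [similarity_transform].
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return list with `image` (transformed matrix, same `H x W`) and `valid`
#'   (logical matrix, `TRUE` where the pixel sampled inside the source).
#' @export
apply_transform <- function(image, t, interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!is.matrix(image) || !is.numeric(image)) {
    gc_stop("image must be a numeric matrix", "gelcorr_param_error")
  }
  stopifnot(inherits(t, "similarity_transform"))
  h <- nrow(image); w <- ncol(image)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  # output pixel grid, 0-based
  xo <- rep(0:(w - 1), each = h)
  yo <- rep(0:(h - 1), times = w)
  z <- t_complex(t)
  src <- (complex(real = xo - cx - t$tx, imaginary = yo - cy - t$ty)) / z$a
  xs <- Re(src) + cx
  ys <- Im(src) + cy
  eps <- 1e-9   # tolerate float fuzz at the exact footprint boundary
  valid <- xs >= -eps & xs <= (w - 1) + eps & ys >= -eps & ys <= (h - 1) + eps
  out <- numeric(h * w)
  if (interpolation == "nearest") {
    xi <- pmin(pmax(round(xs), 0), w - 1)
    yi <- pmin(pmax(round(ys), 0), h - 1)
    idx <- yi + 1 + xi * h
    out[valid] <- image[idx[valid]]
  } else {
    x0 <- pmin(pmax(floor(xs), 0), w - 1)
    y0 <- pmin(pmax(floor(ys), 0), h - 1)
    x1 <- pmin(x0 + 1, w - 1)
    y1 <- pmin(y0 + 1, h - 1)
    fx <- pmin(pmax(xs - x0, 0), 1)
    fy <- pmin(pmax(ys - y0, 0), 1)
    i00 <- y0 + 1 + x0 * h; i01 <- y0 + 1 + x1 * h
    i10 <- y1 + 1 + x0 * h; i11 <- y1 + 1 + x1 * h
    v <- (1 - fy) * ((1 - fx) * image[i00] + fx * image[i01]) +
         fy       * ((1 - fx) * image[i10] + fx * image[i11])
    out[valid] <- v[valid]
  }
  list(image = matrix(out, h, w), valid = matrix(valid, h, w))
}

#' Estimate a similarity transform from landmark pairs
#'
#' Least-squares fit of the 4-parameter similarity mapping `src` points onto
#' `dst` points (closed-form complex-regression solution; globally optimal in
#' the least-squares sense). Landmarks are typically picked on the
#' fluorescent standard images of two gels. The RMS residual is logged.
#'
#' @param src,dst numeric matrices `n x 2` of (x, y) coordinates (0-based
#'   pixel convention), `n >= 2`.
#' @param dim_hw image dimensions `c(H, W)` fixing the rotation center used
#'   by the returned parameterization.
#' @return a [similarity_transform].
#' @export
estimate_from_landmarks <- function(src, dst, dim_hw) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 2 || nrow(dst) != nrow(src) || ncol(src) != 2 || ncol(dst) != 2) {
    gc_stop("need >= 2 (x, y) landmark pairs of equal count", "gelcorr_estimation_error")
  }
  z <- complex(real = src[, 1], imaginary = src[, 2])
  w <- complex(real = dst[, 1], imaginary = dst[, 2])
  zc <- z - mean(z); wc <- w - mean(w)
  denom <- sum(Mod(zc)^2)
  if (denom < 1e-12) {
    gc_stop("degenerate landmarks: all source points coincide", "gelcorr_estimation_error")
  }
  a <- sum(Conj(zc) * wc) / denom
  if (Mod(a) < 1e-12) {
    gc_stop("degenerate landmarks: zero-scale fit", "gelcorr_estimation_error")
  }
  b <- mean(w) - a * mean(z)
  cx <- (dim_hw[2] - 1) / 2; cy <- (dim_hw[1] - 1) / 2
  cc <- complex(real = cx, imaginary = cy)
  tt <- b - cc + a * cc
  fit <- similarity_transform(-Arg(a) * 180 / pi, Mod(a), Re(tt), Im(tt))
  pred <- a * z + b
  rms <- sqrt(mean(Mod(w - pred)^2))
  gc_info(sprintf("landmark fit: rot=%.4f deg scale=%.6f t=(%.3f, %.3f), RMS residual %.4g px",
                  fit$rotation_deg, fit$scale, fit$tx, fit$ty, rms))
  fit
}

#' Alignment set: per-sample transforms to a reference image
#'
#' @param reference_id sample id of the reference image (its transform is the
#'   identity).
#' @param transforms named list of [similarity_transform]s, keyed by
#'   sample id. Samples without an entry default to the identity.
#' @return object of class `alignment_set`.
#' @export
alignment_set <- function(reference_id, transforms = list()) {
  if (!is.list(transforms) ||
      (length(transforms) && is.null(names(transforms)))) {
    gc_stop("transforms must be a named list", "gelcorr_param_error")
  }
  for (t in transforms) stopifnot(inherits(t, "similarity_transform"))
  ref <- transforms[[reference_id]]
  if (!is.null(ref) &&
      !isTRUE(all.equal(unclass(ref), unclass(identity_transform())))) {
    gc_stop("the reference sample's transform must be the identity", "gelcorr_param_error")
  }
  structure(list(reference_id = reference_id, transforms = transforms),
            class = "alignment_set")
}

#' Read / write an alignment set
#'
#' JSON layout: `{"reference_id": id, "transforms": {id: {"rotation_deg": r,
#' "scale": s, "tx": x, "ty": y}, ...}}`. A CSV with columns `sample_id,
#' rotation_deg, scale, tx, ty` is also accepted (the reference is then the
#' first identity row, or must be passed explicitly).
#'
#' @param path JSON or CSV file path.
#' @param reference_id reference sample id, required for CSV input without an
#'   identity row.
#' @return an [alignment_set].
#' @export
read_alignment <- function(path, reference_id = NULL) {
  if (!file.exists(path)) gc_stop(sprintf("alignment file not found: %s", path),
                                  "gelcorr_io_error")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    tr <- lapply(obj$transforms, function(x) {
      similarity_transform(x$rotation_deg, x$scale, x$tx, x$ty)
    })
    alignment_set(obj$reference_id, tr)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    tr <- setNames(lapply(seq_len(nrow(df)), function(i) {
      similarity_transform(df$rotation_deg[i], df$scale[i], df$tx[i], df$ty[i])
    }), df$sample_id)
    if (is.null(reference_id)) {
      is_id <- vapply(tr, function(t) {
        t$rotation_deg == 0 && t$scale == 1 && t$tx == 0 && t$ty == 0
      }, logical(1))
      if (!any(is_id)) gc_stop("CSV alignment has no identity row; pass reference_id",
                               "gelcorr_param_error")
      reference_id <- names(tr)[which(is_id)[1]]
    }
    alignment_set(reference_id, tr)
  }
}

#' @rdname read_alignment
#' @param alignment an [alignment_set] to serialize (JSON).
#' @export
write_alignment <- function(alignment, path) {
  obj <- list(
    reference_id = alignment$reference_id,
    transforms = lapply(alignment$transforms, function(t) {
      list(rotation_deg = t$rotation_deg, scale = t$scale, tx = t$tx, ty = t$ty)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Align every image of a stack to the reference
#'
#' Applies each sample's [similarity_transform] (identity where none is
#' given) and intersects the resampled validity with the stack's existing
#' mask, so pixels pushed outside any image's footprint become missing data
#' for the whole downstream analysis of that sample.
#'
#' @param stack a [gel_stack].
#' @param alignment an [alignment_set] covering the stack's samples.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return the aligned [gel_stack].
#' @export
align_stack <- function(stack, alignment, interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(stack, "gel_stack"), inherits(alignment, "alignment_set"))
  unknown <- setdiff(names(alignment$transforms), stack$sample_ids)
  if (length(unknown)) {
    gc_stop(sprintf("alignment references unknown sample(s): %s",
                    paste(unknown, collapse = ", ")), "gelcorr_id_error")
  }
  out <- stack
  for (i in seq_along(stack$sample_ids)) {
    id <- stack$sample_ids[i]
    t <- alignment$transforms[[id]]
    if (is.null(t)) t <- identity_transform()
    r <- apply_transform(stack$data[, , i], t, interpolation)
    out$data[, , i] <- r$image
    out$valid[, , i] <- stack$valid[, , i] & r$valid
  }
  out
}

#' Blend two images into an alignment-QC overlay
#'
#' Non-interactive replacement for fading between the image under alignment
#' and the reference: each input is min-max scaled to `[0, 1]` and blended as
#' `(1 - alpha) * A + alpha * B`, suitable for export as an 8-bit PNG.
#'
#' @param image_a,image_b numeric matrices of identical shape.
#' @param alpha blend weight in `[0, 1]` (0 = pure A, 1 = pure B).
#' @return numeric matrix in `[0, 1]`.
#' @export
render_overlay <- function(image_a, image_b, alpha = 0.5) {
  if (!identical(dim(image_a), dim(image_b))) {
    gc_stop("overlay inputs must have identical dimensions", "gelcorr_dim_error")
  }
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    gc_stop("alpha must lie in [0, 1]", "gelcorr_param_error")
  }
  minmax <- function(m) {
    rng <- range(m)
    if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  }
  (1 - alpha) * minmax(image_a) + alpha * minmax(image_b)
}
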