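#' Synthetic gel spot specification
#'
#' One anisotropic Gaussian spot whose amplitude responds linearly to the
#' external covariate: `amplitude(v) = max(0, base_amplitude + slope * v)`,
#' optionally zeroed outside the covariate window `[appear_at,
#' disappear_at]` to emulate spots that appear or vanish during a response
#' (as isoform chains do when a protein is modified). Real gel spots are
#' irregular, but the pixel-based pipeline is shape-agnostic, so Gaussian
#' profiles suffice for ground truth.
#'
#' @param cx,cy spot center in 0-based pixel coordinates (x = column,
#'   y = row).
#' @param sx,sy Gaussian widths in pixels, both `> 0`.
#' @param base_amplitude amplitude at covariate 0, `>= 0`.
#' @param slope amplitude change per unit covariate (may be negative).
#' @param appear_at,disappear_at optional covariate thresholds outside which
#'   the spot is absent.
#' @return object of class `spot_spec`.
#' @export
spot_spec <- function(cx, cy, sx, sy, base_amplitude, slope = 0,
                      appear_at = NULL, disappear_at = NULL) {
  if (sx <= 0 || sy <= 0) gc_stop("spot widths must be > 0", "gelcorr_param_error")
  if (base_amplitude < 0) gc_stop("base_amplitude must be >= 0", "gelcorr_param_error")
  structure(list(cx = cx, cy = cy, sx = sx, sy = sy,
                 base_amplitude = base_amplitude, slope = slope,
                 appear_at = appear_at, disappear_at = disappear_at),
            class = "spot_spec")
}

#' Synthetic streak specification
#'
#' A horizontal streak (one pixel row over a column range) emulating the
#' characteristic streaking/laddering of heavily modified proteins, e.g.
#' ubiquitination ladders. Amplitude responds linearly to the covariate like
#' a spot's.
#'
#' @param y pixel row (0-based).
#' @param x_start,x_end inclusive 0-based column range, `x_start <= x_end`.
#' @param amplitude base amplitude, `>= 0`.
#' @param slope amplitude change per covariate unit.
#' @return object of class `streak_spec`.
#' @export
streak_spec <- function(y, x_start, x_end, amplitude, slope = 0) {
  if (x_start > x_end) gc_stop("x_start must be <= x_end", "gelcorr_param_error")
  if (amplitude < 0) gc_stop("amplitude must be >= 0", "gelcorr_param_error")
  structure(list(y = y, x_start = x_start, x_end = x_end,
                 amplitude = amplitude, slope = slope),
            class = "streak_spec")
}

#' Synthetic gel-stack specification
#'
#' Full recipe for a stack of gel-like images with known ground truth:
#' covariate-responsive Gaussian spot chains, streaks, per-image global
#' intensity jitter (the nuisance normalization removes), additive Gaussian
#' noise, and known per-image misalignments (the nuisance alignment
#' removes). Rendering is deterministic given `seed`.
#'
#' The image model for sample `i` with covariate value `v_i` is
#' `scale_i * (background + spots(v_i) + streaks(v_i)) + noise`, then the
#' misalignment transform is applied and values are clamped at 0 (mimicking
#' non-negative chemiluminescence counts).
#'
#' @param h,w image dimensions in pixels.
#' @param covariate_values numeric vector, one value per sample.
#' @param spots list of [spot_spec()]s.
#' @param streaks list of [streak_spec()]s.
#' @param background_level constant background intensity.
#' @param noise_sd additive Gaussian noise standard deviation, `>= 0`.
#' @param per_image_scale positive per-sample global intensity factors
#'   (default all 1).
#' @param noise_stage `"post_scale"` (default): noise is added after the
#'   per-image scale, emulating camera/readout noise with a fixed floor;
#'   `"pre_scale"`: noise is part of the scene and scales with the image,
#'   emulating blot-level variability. The distinction matters under strong
#'   scale jitter: a fixed noise floor shifts each image's median by
#'   `~noise_sd/scale` and so leaves a small systematic trend that no
#'   per-image rescaling can remove, whereas scene-level noise cancels
#'   exactly under mean/median normalization.
#' @param misalignments list of per-sample [similarity_transform()]s
#'   (default all identity).
#' @param seed integer seed making every rendering reproducible.
#' @param covariate_name name used for the covariate column in written
#'   manifests.
#' @return object of class `synthetic_stack_spec`.
#' @export
synthetic_stack_spec <- function(h, w, covariate_values, spots = list(),
                                 streaks = list(), background_level = 0,
                                 noise_sd = 0, per_image_scale = NULL,
                                 misalignments = NULL, seed = 1L,
                                 covariate_name = "covariate",
                                 noise_stage = c("post_scale", "pre_scale")) {
  noise_stage <- match.arg(noise_stage)
  n <- length(covariate_values)
  if (n < 2) gc_stop("need at least 2 covariate values", "gelcorr_param_error")
  if (is.null(per_image_scale)) per_image_scale <- rep(1, n)
  if (is.null(misalignments)) {
    misalignments <- replicate(n, identity_transform(), simplify = FALSE)
  }
  if (length(per_image_scale) != n || length(misalignments) != n) {
    gc_stop("per-sample vectors must match length(covariate_values)",
            "gelcorr_param_error")
  }
  if (any(per_image_scale <= 0)) {
    gc_stop("per_image_scale must be positive", "gelcorr_param_error")
  }
  if (noise_sd < 0) gc_stop("noise_sd must be >= 0", "gelcorr_param_error")
  for (s in spots) stopifnot(inherits(s, "spot_spec"))
  for (s in streaks) stopifnot(inherits(s, "streak_spec"))
  for (t in misalignments) stopifnot(inherits(t, "similarity_transform"))
  structure(list(h = h, w = w, covariate_values = covariate_values,
                 spots = spots, streaks = streaks,
                 background_level = background_level, noise_sd = noise_sd,
                 per_image_scale = per_image_scale,
                 misalignments = misalignments, seed = as.integer(seed),
                 covariate_name = covariate_name, noise_stage = noise_stage),
            class = "synthetic_stack_spec")
}

spot_amplitude <- function(spot, v) {
  if (!is.null(spot$appear_at) && v < spot$appear_at) return(0)
  if (!is.null(spot$disappear_at) && v > spot$disappear_at) return(0)
  max(spot$base_amplitude + spot$slope * v, 0)
}

gaussian_field <- function(h, w, cx, cy, sx, sy) {
  gx <- exp(-((0:(w - 1)) - cx)^2 / (2 * sx^2))
  gy <- exp(-((0:(h - 1)) - cy)^2 / (2 * sy^2))
  outer(gy, gx)
}

## noise-free scene for sample i, in the true (aligned) geometry
render_scene <- function(spec, i) {
  v <- spec$covariate_values[i]
  img <- matrix(spec$background_level, spec$h, spec$w)
  for (s in spec$spots) {
    a <- spot_amplitude(s, v)
    if (a > 0) img <- img + a * gaussian_field(spec$h, spec$w, s$cx, s$cy, s$sx, s$sy)
  }
  for (s in spec$streaks) {
    a <- max(s$amplitude + s$slope * v, 0)
    if (a > 0) img[s$y + 1, (s$x_start:s$x_end) + 1] <-
        img[s$y + 1, (s$x_start:s$x_end) + 1] + a
  }
  img
}

#' Render one synthetic gel image
#'
#' Applies the full observation model for sample `i`: scene rendering,
#' per-image intensity scale, additive noise, the sample's misalignment
#' transform, and clamping at zero. Deterministic for a given spec and
#' sample index. The returned matrix carries the misalignment's validity
#' footprint as attribute `"valid"`.
#'
#' @param spec a [synthetic_stack_spec].
#' @param i sample index.
#' @return numeric `h x w` matrix.
#' @export
render_image <- function(spec, i) {
  stopifnot(inherits(spec, "synthetic_stack_spec"))
  n <- length(spec$covariate_values)
  if (i < 1 || i > n) gc_stop("invalid sample index", "gelcorr_param_error")
  img <- render_scene(spec, i)
  noise <- if (spec$noise_sd > 0) {
    with_seed((as.numeric(spec$seed) + i * 100003) %% 2147483647,
              matrix(rnorm(spec$h * spec$w, 0, spec$noise_sd), spec$h, spec$w))
  } else 0
  img <- if (identical(spec$noise_stage, "pre_scale")) {
    spec$per_image_scale[i] * (img + noise)
  } else {
    spec$per_image_scale[i] * img + noise
  }
  t <- spec$misalignments[[i]]
  r <- apply_transform(img, t, "bilinear")
  out <- pmax(r$image, 0)
  attr(out, "valid") <- r$valid
  out
}

## ground-truth fields in the true (aligned) geometry:
## - sign_field: per-pixel effective covariate response (signed slope sum)
## - responsive_mask: |sign_field| >= half its maximum (half-max rule)
## - background_mask: total signal envelope below 1% of its maximum
ground_truth_fields <- function(spec) {
  v <- spec$covariate_values
  dv <- max(v) - min(v)
  sign_field <- matrix(0, spec$h, spec$w)
  envelope <- matrix(0, spec$h, spec$w)
  for (s in spec$spots) {
    amps <- vapply(v, function(vi) spot_amplitude(s, vi), numeric(1))
    eff_slope <- (amps[which.max(v)] - amps[which.min(v)]) / dv
    g <- gaussian_field(spec$h, spec$w, s$cx, s$cy, s$sx, s$sy)
    sign_field <- sign_field + eff_slope * g
    envelope <- envelope + max(amps) * g
  }
  for (s in spec$streaks) {
    amps <- pmax(s$amplitude + s$slope * v, 0)
    eff_slope <- (amps[which.max(v)] - amps[which.min(v)]) / dv
    cols <- (s$x_start:s$x_end) + 1
    sign_field[s$y + 1, cols] <- sign_field[s$y + 1, cols] + eff_slope
    envelope[s$y + 1, cols] <- envelope[s$y + 1, cols] + max(amps)
  }
  mx <- max(abs(sign_field))
  responsive <- if (mx > 0) abs(sign_field) >= 0.5 * mx else sign_field != 0
  bg <- envelope < 0.01 * max(envelope, 1e-12)
  list(sign_field = sign_field, envelope = envelope,
       responsive_mask = responsive, background_mask = bg)
}

#' Generate a synthetic gel stack with ground truth
#'
#' Renders every sample of the spec into a [gel_stack] (sample ids `s1`,
#' `s2`, ...; validity from each misalignment's footprint) and returns the
#' ground truth needed to score a pipeline against it: the exact
#' misalignment transforms and their inverses (the corrections an aligner
#' should recover), the signed per-pixel response field, the half-max
#' responsive mask (where covariate-driven amplitude change is at least half
#' its image-wide maximum) and the pure-background mask.
#'
#' @param spec a [synthetic_stack_spec].
#' @return list with `stack` (a [gel_stack]) and `ground_truth` (list:
#'   `misalignments`, `corrections`, `sign_field`, `responsive_mask`,
#'   `background_mask`, `envelope`).
#' @export
generate_stack <- function(spec) {
  stopifnot(inherits(spec, "synthetic_stack_spec"))
  n <- length(spec$covariate_values)
  imgs <- vector("list", n)
  valid <- array(TRUE, dim = c(spec$h, spec$w, n))
  for (i in seq_len(n)) {
    im <- render_image(spec, i)
    valid[, , i] <- attr(im, "valid")
    attr(im, "valid") <- NULL
    imgs[[i]] <- im
  }
  stack <- gel_stack(imgs, paste0("s", seq_len(n)))
  stack$valid <- valid
  gt <- ground_truth_fields(spec)
  gt$misalignments <- spec$misalignments
  gt$corrections <- lapply(spec$misalignments, invert)
  list(stack = stack, ground_truth = gt)
}

#' Synthetic p53-like irradiation time course
#'
#' A 5-sample stack emulating a p53 stabilization time course (covariate =
#' hours after irradiation, 0/2/4/6/8): a horizontal chain of five
#' full-length-protein spots of which the three right-most respond strongly,
#' a high-PI "long tail" region and a late-appearing spot (appearing only
#' from 4 h), two weak lower isoform spots, ladder-like streaks, per-gel
#' intensity jitter, 5% additive noise and small per-gel misalignments
#' (rotation/scale/translation; sample 1 is the reference).
#'
#' @param seed RNG seed for the noise.
#' @param misaligned include the per-image misalignments (set `FALSE` for an
#'   already-aligned stack).
#' @return a [synthetic_stack_spec].
#' @export
preset_p53_timecourse <- function(seed = 101L, misaligned = TRUE) {
  spots <- list(
    # full-length chain at 53 kDa: left two spots barely respond
    spot_spec(26, 38, 4.5, 3.5, 140, 3),
    spot_spec(36, 38, 4.5, 3.5, 140, 3),
    spot_spec(46, 38, 4.5, 3.5, 50, 24),
    spot_spec(56, 38, 4.5, 3.5, 50, 24),
    spot_spec(66, 38, 4.5, 3.5, 50, 24),
    # "long tail" towards high PI, develops with stimulation
    spot_spec(74, 38, 6, 3, 10, 22),
    # new spot appearing mid-course
    spot_spec(84, 38, 4, 3, 0, 18, appear_at = 3),
    # weak p53 beta/gamma isoforms below left
    spot_spec(22, 54, 3, 2.5, 20, 5),
    spot_spec(30, 54, 3, 2.5, 20, 5)
  )
  streaks <- list(
    # ubiquitination-ladder style streaks above the main chain
    streak_spec(20, 40, 70, 6, 4),
    streak_spec(26, 40, 70, 6, 4),
    streak_spec(32, 40, 70, 6, 4)
  )
  mis <- if (misaligned) list(
    identity_transform(),
    similarity_transform(1.5, 1.01, 2.5, -1.5),
    similarity_transform(-2.0, 0.99, -3.0, 2.0),
    similarity_transform(1.0, 1.02, 1.5, 2.5),
    similarity_transform(-1.0, 0.985, -2.0, -2.8)
  ) else NULL
  # noise at ~5% of the peak covariate-driven amplitude range (~260 counts)
  synthetic_stack_spec(
    h = 96, w = 96, covariate_values = c(0, 2, 4, 6, 8),
    spots = spots, streaks = streaks,
    background_level = 30, noise_sd = 13,
    per_image_scale = c(1.0, 1.25, 0.85, 1.1, 0.95),
    misalignments = mis, seed = seed, covariate_name = "hours"
  )
}

#' Synthetic stack with pure per-image scale jitter
#'
#' Non-responsive (slope 0) spots under strong global intensity jitter that
#' grows monotonically with the covariate, spanning a factor of 16. Without
#' normalization every signal pixel correlates spuriously with the covariate
#' (the jitter masquerades as response, rho near 1); per-image mean/median
#' normalization cancels the jitter exactly, leaving only noise. The sample
#' size (24) is large enough that the null mean of the absolute Spearman
#' correlation (about `sqrt(2 / (pi * (n - 1)))`, 0.165 at n = 24) is
#' comfortably below 0.2, making "no residual correlation" a testable bound.
#'
#' @param seed RNG seed.
#' @param n number of images.
#' @return a [synthetic_stack_spec].
#' @export
preset_scale_jitter <- function(seed = 202L, n = 24L) {
  spots <- list(
    spot_spec(20, 24, 4, 3, 120, 0),
    spot_spec(34, 24, 4, 3, 80, 0),
    spot_spec(26, 40, 5, 4, 100, 0)
  )
  synthetic_stack_spec(
    h = 64, w = 64, covariate_values = seq_len(n),
    spots = spots, background_level = 25, noise_sd = 2,
    per_image_scale = 16^((seq_len(n) - 1) / (n - 1)),
    seed = seed, covariate_name = "step", noise_stage = "pre_scale"
  )
}

spec_to_list <- function(spec) {
  list(
    h = spec$h, w = spec$w, covariate_values = spec$covariate_values,
    covariate_name = spec$covariate_name,
    background_level = spec$background_level, noise_sd = spec$noise_sd,
    per_image_scale = spec$per_image_scale, seed = spec$seed,
    noise_stage = spec$noise_stage,
    spots = lapply(spec$spots, unclass),
    streaks = lapply(spec$streaks, unclass),
    misalignments = lapply(spec$misalignments, unclass)
  )
}

#' Write a synthetic stack to disk as a loadable fixture
#'
#' Writes 16-bit PNG images, a CSV manifest in the [read_manifest()] dialect
#' (covariate column named per the spec), an alignment JSON holding the
#' *correction* transforms (inverses of the generating misalignments, ready
#' for [align_stack()]), and a ground-truth JSON with the exact generating
#' parameters. Loading the manifest reproduces the stack exactly after
#' 16-bit integer quantization.
#'
#' @param spec a [synthetic_stack_spec].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_stack_spec"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  gen <- generate_stack(spec)
  n <- n_samples(gen$stack)
  ids <- gen$stack$sample_ids
  rel <- file.path("images", paste0(ids, ".png"))
  for (i in seq_len(n)) {
    write_gel_png(pmin(gen$stack$data[, , i], 65535), file.path(dir, rel[i]), 16L)
  }
  mf <- data.frame(sample_id = ids, signal_path = rel,
                   standard_path = rel,   # same geometry; stands in for a standard
                   include = rep(TRUE, n), check.names = FALSE,
                   stringsAsFactors = FALSE)
  mf[[spec$covariate_name]] <- as.character(spec$covariate_values)
  attr(mf, "variables") <- spec$covariate_name
  manifest_path <- file.path(dir, "manifest.csv")
  write_manifest(mf, manifest_path)
  corrections <- setNames(lapply(spec$misalignments, invert), ids)
  is_id <- vapply(corrections, function(t) {
    t$rotation_deg == 0 && t$scale == 1 && t$tx == 0 && t$ty == 0
  }, logical(1))
  if (!any(is_id)) {
    gc_stop("no sample has an identity misalignment to serve as reference",
            "gelcorr_param_error")
  }
  write_alignment(alignment_set(ids[which(is_id)[1]], corrections),
                  file.path(dir, "alignment.json"))
  jsonlite::write_json(spec_to_list(spec), file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest_path)
}
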