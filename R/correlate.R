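#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of average-ranked values (midranks for ties). With no
#' ties this equals the classical `1 - 6 * sum(d^2) / (n * (n^2 - 1))`. Rank
#' correlation is the method's workhorse: it is invariant to any strictly
#' monotone transform of either variable, which is what makes ordered
#' categories (encoded as consecutive integers) legitimate inputs.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, each with at least
#'   two distinct values.
#' @return correlation in `[-1, 1]`.
#' @examples
#' spearman_rho(1:5, c(10, 20, 30, 40, 50))  # 1
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))       # 0.8
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) {
    gc_stop("x and y must have equal length >= 3", "gelcorr_param_error")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    gc_stop("x and y must be finite", "gelcorr_param_error")
  }
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) {
    gc_stop("correlation undefined: constant vector", "gelcorr_undefined_error")
  }
  sum(dx * dy) / den
}

#' Significance-test configuration for per-pixel correlations
#'
#' @param test `"permutation"` (default) or `"t_test"`.
#' @param n_permutations Monte Carlo sample size when exhaustive enumeration
#'   is infeasible; at least 99.
#' @param exhaustive_limit enumerate all `n!` orderings whenever
#'   `factorial(n) <= exhaustive_limit` (default 40320 = 8!, i.e. exact for
#'   up to 8 samples; the typical gel time course of 5 samples has only 120
#'   orderings, so its permutation p is exact).
#' @param seed RNG seed for Monte Carlo permutations.
#' @return object of class `test_config`. Tests are always two-sided: both
#'   activation and suppression of a gel region are meaningful.
#' @export
test_config <- function(test = c("permutation", "t_test"),
                        n_permutations = 999L, exhaustive_limit = 40320L,
                        seed = 1L) {
  test <- match.arg(test)
  if (n_permutations < 99) gc_stop("n_permutations must be >= 99", "gelcorr_param_error")
  if (exhaustive_limit < 2) gc_stop("exhaustive_limit must be >= 2", "gelcorr_param_error")
  structure(list(test = test, n_permutations = as.integer(n_permutations),
                 exhaustive_limit = as.numeric(exhaustive_limit),
                 seed = as.integer(seed), sidedness = "two_sided"),
            class = "test_config")
}

#' Two-sided correlation t-test p-value
#'
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` referred to a Student-t
#' distribution with `n - 2` degrees of freedom. `|rho| = 1` clamps to the
#' smallest representable positive p.
#'
#' @param rho correlation value(s) in `[-1, 1]` (vectorized).
#' @param n number of samples, `n >= 4`.
#' @return p-value(s) in `(0, 1]`.
#' @export
p_ttest <- function(rho, n) {
  if (n < 4) gc_stop("t-test needs n >= 4 (df = n - 2 >= 2)", "gelcorr_param_error")
  if (any(abs(rho) > 1 + 1e-12, na.rm = TRUE)) {
    gc_stop("|rho| must be <= 1", "gelcorr_param_error")
  }
  r <- pmin(pmax(rho, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(-abs(t), df = n - 2)
  p[abs(r) == 1] <- 0
  out <- pmin(pmax(p, .Machine$double.xmin), 1)
  out[is.na(rho)] <- NA_real_
  out
}

## all-permutation index matrix (rows = orderings); exhaustive when
## n! <= limit, otherwise `m` uniform random permutations drawn under `seed`
perm_index_matrix <- function(n, exhaustive, m = NULL, seed = NULL) {
  if (exhaustive) {
    e1071::permutations(n)
  } else {
    with_seed(seed, t(replicate(m, sample.int(n))))
  }
}

#' Permutation-test p-value for a Spearman correlation
#'
#' The null is generated by permuting `y`: exhaustive enumeration of all `n!`
#' orderings when `factorial(n) <= cfg$exhaustive_limit` (two-sided
#' `p = #{|rho_perm| >= |rho_obs|} / n!`, exact), otherwise
#' `cfg$n_permutations` uniform random orderings with the observed ordering
#' included (`p = (b + 1) / (m + 1)`). Midranks are recomputed per
#' permutation, i.e. ties travel with the permuted `y` values.
#'
#' @param x,y numeric vectors as in [spearman_rho()].
#' @param cfg a [test_config].
#' @return p-value in `(0, 1]`.
#' @examples
#' p_permutation(1:4, 1:4, test_config())        # 2/24: only the two
#' p_permutation(1:5, c(2, 4, 6, 8, 10), test_config())  # extremes reach |rho|=1
#' @export
p_permutation <- function(x, y, cfg = test_config()) {
  stopifnot(inherits(cfg, "test_config"))
  n <- length(x)
  rho_obs <- spearman_rho(x, y)
  exhaustive <- factorial(n) <= cfg$exhaustive_limit
  P <- perm_index_matrix(n, exhaustive, cfg$n_permutations, cfg$seed)
  rx <- rank(x)
  rho_null <- apply(P, 1, function(idx) {
    ry <- rank(y[idx])
    dx <- rx - mean(rx); dy <- ry - mean(ry)
    den <- sqrt(sum(dx^2) * sum(dy^2))
    if (den == 0) return(0)
    sum(dx * dy) / den
  })
  b <- sum(abs(rho_null) >= abs(rho_obs) - 1e-12)
  p <- if (exhaustive) b / nrow(P) else (b + 1) / (nrow(P) + 1)
  min(max(p, .Machine$double.xmin), 1)
}

## flatten a stack into pixel-column form: X (npix x n) and V (npix x n)
pixel_columns <- function(stack) {
  d <- dim(stack$data)
  list(X = matrix(stack$data, ncol = d[3]),
       V = matrix(stack$valid, ncol = d[3]),
       h = d[1], w = d[2], n = d[3])
}

#' Per-pixel Spearman correlation map
#'
#' Correlates each pixel column (the vector of intensities at one (x, y)
#' across the stack) with the external variable. Pixels with fewer than
#' `min_valid` valid samples, or a constant intensity column (rank
#' correlation undefined), are masked: `NaN` in the map, `FALSE` in the
#' validity matrix.
#'
#' @param stack a (normalized, aligned) [gel_stack].
#' @param variable an `external_variable` or numeric vector, one value per
#'   stack sample.
#' @param min_valid minimum number of valid samples per pixel; default all
#'   samples (`n`), relaxable down to 3.
#' @return list with matrices `rho` and `validity`.
#' @export
correlation_map <- function(stack, variable, min_valid = NULL) {
  yv <- if (inherits(variable, "external_variable")) variable$values else variable
  pc <- pixel_columns(stack)
  if (length(yv) != pc$n) {
    gc_stop("variable length must equal the number of stack images", "gelcorr_param_error")
  }
  if (length(unique(yv)) < 2) {
    gc_stop("external variable has fewer than 2 distinct values", "gelcorr_param_error")
  }
  if (is.null(min_valid)) min_valid <- pc$n
  min_valid <- max(3L, as.integer(min_valid))
  rho <- pixel_rho(pc, yv, min_valid)
  list(rho = matrix(rho, pc$h, pc$w),
       validity = matrix(is.finite(rho), pc$h, pc$w))
}

## core vectorized rho over pixel columns; returns vector with NaN at
## masked pixels (too few valid samples or constant column)
pixel_rho <- function(pc, yv, min_valid) {
  X <- pc$X; V <- pc$V; n <- pc$n
  rho <- rep(NaN, nrow(X))
  nv <- rowSums(V)
  full <- (nv == n) & (n >= min_valid)
  if (any(full)) {
    RX <- row_ranks(X[full, , drop = FALSE])
    ry <- rank(yv)
    dyc <- ry - mean(ry)
    rxc <- RX - rowMeans(RX)
    den <- sqrt(rowSums(rxc^2) * sum(dyc^2))
    r <- as.vector(rxc %*% dyc) / den
    r[den == 0] <- NaN
    rho[full] <- r
  }
  partial <- which(!full & nv >= min_valid & nv < n)
  for (i in partial) {
    keep <- V[i, ]
    yi <- yv[keep]
    if (length(unique(yi)) < 2) next
    r <- tryCatch(spearman_rho(X[i, keep], yi),
                  gelcorr_error = function(e) NaN)
    rho[i] <- r
  }
  rho
}

row_ranks <- function(m) {
  if (nrow(m) == 0) return(m)
  t(apply(m, 1, rank))
}

#' Normalized standard deviation map
#'
#' Per-pixel sample standard deviation (divisor `n - 1`) of the normalized
#' intensities, divided by the maximum such value over all valid pixels, so
#' the map lies in `[0, 1]` with the most variable pixel at exactly 1. This
#' is the "variance" factor of the composite biosignature: it suppresses
#' regions whose correlation is strong but whose intensity barely moves.
#'
#' An alternative definition is selectable with `kind = "cv"`: the per-pixel
#' coefficient of variation (sample sd divided by the absolute mean), again
#' scaled by its global maximum into `[0, 1]`. It emphasizes relative rather
#' than absolute intensity change; pixels with near-zero mean are masked
#' there.
#'
#' @param stack a (normalized) [gel_stack].
#' @param min_valid minimum valid samples per pixel (default all).
#' @param kind `"scaled_sd"` (default) or `"cv"`.
#' @return numeric matrix in `[0, 1]` with `NaN` at masked pixels.
#' @export
sigma_norm_map <- function(stack, min_valid = NULL, kind = c("scaled_sd", "cv")) {
  kind <- match.arg(kind)
  pc <- pixel_columns(stack)
  if (is.null(min_valid)) min_valid <- pc$n
  min_valid <- max(2L, as.integer(min_valid))
  nv <- rowSums(pc$V)
  if (all(nv == 0)) gc_stop("all pixels invalid", "gelcorr_degenerate_error")
  sdv <- rep(NaN, nrow(pc$X))
  full <- nv == pc$n
  if (any(full)) {
    Xf <- pc$X[full, , drop = FALSE]
    mu <- rowMeans(Xf)
    sdv[full] <- sqrt(rowSums((Xf - mu)^2) / (pc$n - 1))
  }
  partial <- which(!full & nv >= min_valid)
  for (i in partial) sdv[i] <- sd(pc$X[i, pc$V[i, ]])
  if (kind == "cv") {
    mu <- rep(NaN, nrow(pc$X))
    if (any(full)) mu[full] <- rowMeans(pc$X[full, , drop = FALSE])
    for (i in partial) mu[i] <- mean(pc$X[i, pc$V[i, ]])
    sdv <- ifelse(abs(mu) > 1e-12, sdv / abs(mu), NaN)
  }
  mx <- suppressWarnings(max(sdv, na.rm = TRUE))
  out <- if (is.finite(mx) && mx > 0) sdv / mx else ifelse(is.finite(sdv), 0, sdv)
  matrix(out, pc$h, pc$w)
}

#' Composite product map
#'
#' Element-wise product of named result maps, e.g. the biosignature
#' `CSD = correlation x significance x variance`. The factor `"significance"`
#' is derived from the p map as `1 - p` (default, keeping every factor in
#' `[0, 1]`) or `-log10(p)` (unbounded). `NaN` propagates.
#'
#' @param maps named list of co-registered matrices (typically `rho`,
#'   `sigma_norm`, `p`).
#' @param formula character vector of factor names, each either a name in
#'   `maps` or `"significance"`.
#' @param p_to_significance `"one_minus_p"` or `"neg_log10_p"`.
#' @return numeric matrix.
#' @export
product_map <- function(maps, formula,
                        p_to_significance = c("one_minus_p", "neg_log10_p")) {
  p_to_significance <- match.arg(p_to_significance)
  out <- NULL
  for (f in formula) {
    m <- if (f == "significance") {
      if (is.null(maps$p)) gc_stop("significance factor requires a 'p' map",
                                   "gelcorr_param_error")
      if (p_to_significance == "one_minus_p") 1 - maps$p else -log10(maps$p)
    } else if (!is.null(maps[[f]])) {
      maps[[f]]
    } else {
      gc_stop(sprintf("unknown factor name '%s'", f), "gelcorr_param_error")
    }
    out <- if (is.null(out)) m else out * m
  }
  out
}

#' Pixel-by-pixel correlation analysis of a gel stack
#'
#' The package's central fitting function, chaining the full analysis:
#' per-image normalization, per-pixel Spearman correlation against the
#' external variable, normalized standard deviation, per-pixel significance
#' (correlation t-test or permutation test), and the composite product maps
#' `CS` (correlation x significance), `CV` (correlation x variance) and the
#' biosignature `CSD` (correlation x significance x variance). The stack is
#' expected to be aligned already (see [align_stack()]).
#'
#' @param stack an aligned [gel_stack].
#' @param variable an `external_variable` from [encode_variable()], or a
#'   numeric vector with one value per stack image.
#' @param scheme normalization scheme (default `"median"`, usually the most
#'   suitable for gel images); see [normalize_image()].
#' @param cfg a [test_config] choosing the significance test.
#' @param min_valid minimum valid samples per pixel (default: all samples).
#' @param p_to_significance mapping from p to the significance factor of
#'   product maps; see [product_map()].
#' @param variance_kind definition of the variability factor,
#'   `"scaled_sd"` (default) or `"cv"`; see [sigma_norm_map()].
#' @return object of class `gel_result`: list with matrices `rho`,
#'   `sigma_norm`, `p`, named list `products` (`CS`, `CV`, `CSD`), logical
#'   `validity`, and `meta` (variable name and values, scheme, test, n, seed,
#'   n_permutations, exhaustive flag, min_valid, significance mapping).
#'   Invalid pixels carry `NaN` in every map.
#' @examples
#' \dontrun{
#' fit <- gel_correlate(stack, encode_variable(m, "hours"),
#'                      cfg = test_config("permutation", seed = 7))
#' summary(fit)
#' }
#' @export
gel_correlate <- function(stack, variable,
                          scheme = c("median", "mean", "zscore", "none"),
                          cfg = test_config(), min_valid = NULL,
                          p_to_significance = c("one_minus_p", "neg_log10_p"),
                          variance_kind = c("scaled_sd", "cv")) {
  scheme <- match.arg(scheme)
  p_to_significance <- match.arg(p_to_significance)
  variance_kind <- match.arg(variance_kind)
  stopifnot(inherits(stack, "gel_stack"), inherits(cfg, "test_config"))
  yv <- if (inherits(variable, "external_variable")) variable$values else variable
  vname <- if (inherits(variable, "external_variable")) variable$name else "variable"

  nstack <- normalize_stack(stack, scheme)
  pc <- pixel_columns(nstack)
  if (length(yv) != pc$n) {
    gc_stop("variable length must equal the number of stack images", "gelcorr_param_error")
  }
  if (length(unique(yv)) < 2) {
    gc_stop("external variable has fewer than 2 distinct values", "gelcorr_param_error")
  }
  if (is.null(min_valid)) min_valid <- pc$n
  min_valid <- max(3L, as.integer(min_valid))

  rho_v <- pixel_rho(pc, yv, min_valid)
  valid <- is.finite(rho_v)

  sig_mat <- sigma_norm_map(nstack, min_valid = max(2L, min_valid),
                            kind = variance_kind)
  sig_v <- as.vector(sig_mat)

  exhaustive <- factorial(pc$n) <= cfg$exhaustive_limit
  p_v <- rep(NaN, length(rho_v))
  if (cfg$test == "t_test") {
    nv <- rowSums(pc$V)
    for (nn in unique(nv[valid])) {
      sel <- valid & nv == nn
      if (nn >= 4) p_v[sel] <- p_ttest(rho_v[sel], nn)
    }
  } else {
    p_v <- permutation_p_map(pc, yv, rho_v, valid, cfg)
  }
  valid <- valid & is.finite(p_v)
  p_v[valid] <- pmin(pmax(p_v[valid], .Machine$double.xmin), 1)

  rho_v[!valid] <- NaN
  sig_v[!valid] <- NaN
  p_v[!valid] <- NaN

  as_map <- function(v) matrix(v, pc$h, pc$w)
  maps <- list(rho = as_map(rho_v), sigma_norm = as_map(sig_v), p = as_map(p_v))
  products <- list(
    CS  = product_map(maps, c("rho", "significance"), p_to_significance),
    CV  = product_map(maps, c("rho", "sigma_norm"), p_to_significance),
    CSD = product_map(maps, c("rho", "significance", "sigma_norm"), p_to_significance)
  )
  structure(list(
    rho = maps$rho, sigma_norm = maps$sigma_norm, p = maps$p,
    products = products, validity = as_map(valid),
    meta = list(variable = vname, values = yv, scheme = scheme,
                test = cfg$test, n = pc$n, seed = cfg$seed,
                n_permutations = if (exhaustive) factorial(pc$n) else cfg$n_permutations,
                exhaustive = exhaustive, min_valid = min_valid,
                significance = p_to_significance)
  ), class = "gel_result")
}

## vectorized permutation p over all full-validity pixels; partial-validity
## pixels fall back to the single-column test with a pixel-derived seed
permutation_p_map <- function(pc, yv, rho_v, valid, cfg) {
  n <- pc$n
  exhaustive <- factorial(n) <= cfg$exhaustive_limit
  P <- perm_index_matrix(n, exhaustive, cfg$n_permutations, cfg$seed)
  K <- nrow(P)
  ry <- rank(yv)
  dyc <- ry - mean(ry)
  sy <- sqrt(sum(dyc^2))
  RyP <- matrix(ry[t(P)], ncol = n, byrow = TRUE)  # ranks of permuted y
  RyPc <- RyP - mean(ry)
  p_v <- rep(NaN, nrow(pc$X))
  nv <- rowSums(pc$V)
  full <- which(nv == n & valid)
  block <- 4096L
  for (s in seq(1, length(full), by = block)) {
    rows <- full[s:min(s + block - 1L, length(full))]
    RX <- row_ranks(pc$X[rows, , drop = FALSE])
    rxc <- RX - rowMeans(RX)
    sx <- sqrt(rowSums(rxc^2))
    rho_null <- (rxc %*% t(RyPc)) / (sx * sy)   # npix_block x K
    cnt <- rowSums(abs(rho_null) >= abs(rho_v[rows]) - 1e-12)
    p_v[rows] <- if (exhaustive) cnt / K else (cnt + 1) / (K + 1)
  }
  partial <- which(nv < n & valid)
  for (i in partial) {
    keep <- pc$V[i, ]
    cfg_i <- cfg
    cfg_i$seed <- as.integer((cfg$seed + i) %% .Machine$integer.max)
    p_v[i] <- tryCatch(
      p_permutation(pc$X[i, keep], yv[keep], cfg_i),
      gelcorr_error = function(e) NaN
    )
  }
  p_v
}

#' Benjamini-Hochberg q-value map
#'
#' Optional extension: the core maps carry raw per-pixel p-values (no
#' multiple-testing correction, matching the per-pixel maps the method
#' reports); this helper converts a result's p map into BH false-discovery
#' q-values over the valid pixels.
#'
#' @param fit a `gel_result`.
#' @return matrix of q-values, `NaN` at invalid pixels.
#' @export
adjust_pvalues <- function(fit) {
  stopifnot(inherits(fit, "gel_result"))
  q <- fit$p
  sel <- is.finite(q)
  q[sel] <- p.adjust(q[sel], method = "BH")
  q
}

#' @export
print.gel_result <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<gel_result> %d x %d maps, n = %d samples, variable '%s'\n",
              nrow(x$rho), ncol(x$rho), m$n, m$variable))
  cat(sprintf("  normalization: %s; test: %s%s (seed %d); valid pixels: %.1f%%\n",
              m$scheme, m$test,
              if (m$test == "permutation")
                sprintf(" (%s, %d permutations)",
                        if (m$exhaustive) "exhaustive" else "Monte Carlo",
                        m$n_permutations) else "",
              m$seed, 100 * mean(x$validity)))
  invisible(x)
}

#' @export
summary.gel_result <- function(object, ...) {
  maps <- c(list(rho = object$rho, sigma_norm = object$sigma_norm, p = object$p),
            object$products)
  stats <- t(vapply(maps, function(m) {
    v <- m[is.finite(m)]
    if (!length(v)) return(c(mean = NaN, min = NaN, max = NaN, n_valid = 0))
    c(mean = mean(v), min = min(v), max = max(v), n_valid = length(v))
  }, numeric(4)))
  out <- list(meta = object$meta, stats = as.data.frame(stats))
  class(out) <- "summary.gel_result"
  out
}

#' @export
print.summary.gel_result <- function(x, ...) {
  cat(sprintf("Pixel-by-pixel correlation analysis: variable '%s', n = %d, %s normalization, %s test\n",
              x$meta$variable, x$meta$n, x$meta$scheme, x$meta$test))
  print(round(x$stats, 4))
  invisible(x)
}

#' Plot result maps as heat maps
#'
#' Draws the rho, sigma, p and CSD maps with diverging (signed maps,
#' symmetric about 0) or sequential (unsigned maps) palettes; invalid pixels
#' are gray.
#'
#' @param x a `gel_result`.
#' @param which map names to draw.
#' @param ... ignored.
#' @export
plot.gel_result <- function(x, which = c("rho", "sigma_norm", "p", "CSD"), ...) {
  maps <- c(list(rho = x$rho, sigma_norm = x$sigma_norm, p = x$p), x$products)
  which <- intersect(which, names(maps))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(which)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  for (nm in which) {
    m <- maps[[nm]]
    signed <- nm %in% c("rho", "CS", "CV", "CSD")
    rgbm <- heatmap_rgb(m, if (signed) "signed" else "unsigned")
    img <- grDevices::as.raster(rgbm)
    graphics::plot(NULL, xlim = c(0, ncol(m)), ylim = c(0, nrow(m)),
                   asp = 1, axes = FALSE, xlab = "", ylab = "", main = nm)
    graphics::rasterImage(img, 0, 0, ncol(m), nrow(m))
  }
  invisible(x)
}
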