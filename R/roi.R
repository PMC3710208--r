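#' Rectangular region of interest
#'
#' Axis-aligned pixel rectangle used to summarize result maps quantitatively,
#' e.g. the mean correlation over a protein's gel region. Coordinates are
#' 0-based with the origin at the top-left pixel; `x` counts columns
#' (rightwards), `y` rows (downwards); the top-left pixel of the ROI is
#' included.
#'
#' @param x0,y0 top-left pixel (inclusive, 0-based).
#' @param width,height extent in pixels, both `>= 1`.
#' @return object of class `gel_roi`.
#' @examples
#' gel_roi(10, 20, 30, 15)
#' @export
gel_roi <- function(x0, y0, width, height) {
  v <- c(x0, y0, width, height)
  if (length(v) != 4 || !all(is.finite(v)) || any(v != round(v))) {
    gc_stop("ROI parameters must be four integers", "gelcorr_param_error")
  }
  if (width < 1 || height < 1 || x0 < 0 || y0 < 0) {
    gc_stop("ROI must have positive size and non-negative origin", "gelcorr_param_error")
  }
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "gel_roi")
}

#' @export
print.gel_roi <- function(x, ...) {
  cat(sprintf("<gel_roi> x0=%d y0=%d width=%d height=%d (0-based, top-left origin)\n",
              x$x0, x$y0, x$width, x$height))
  invisible(x)
}

roi_check_bounds <- function(roi, map_dim) {
  h <- map_dim[1]; w <- map_dim[2]
  if (roi$x0 + roi$width > w || roi$y0 + roi$height > h) {
    gc_stop(sprintf(
      "ROI (x0=%d, y0=%d, %dx%d) exceeds map bounds (%d x %d pixels)",
      roi$x0, roi$y0, roi$width, roi$height, w, h), "gelcorr_roi_error")
  }
}

roi_rows <- function(roi) (roi$y0 + 1):(roi$y0 + roi$height)
roi_cols <- function(roi) (roi$x0 + 1):(roi$x0 + roi$width)

result_maps <- function(fit) {
  c(list(rho = fit$rho, sigma_norm = fit$sigma_norm, p = fit$p), fit$products)
}

#' Summarize result maps over a region of interest
#'
#' NaN-aware mean, min, max and valid-pixel count for every map in a
#' `gel_result`, restricted to the ROI. An ROI with no valid pixels yields
#' `NaN` statistics, `count_valid = 0` and a warning.
#'
#' @param fit a `gel_result` from [gel_correlate()].
#' @param roi a [gel_roi], fully inside the map bounds.
#' @return object of class `roi_summary`: list with `roi` and a data.frame
#'   `stats` (rows = maps; columns `mean`, `min`, `max`, `count_valid`).
#' @export
summarize_roi <- function(fit, roi) {
  stopifnot(inherits(fit, "gel_result"), inherits(roi, "gel_roi"))
  roi_check_bounds(roi, dim(fit$rho))
  maps <- result_maps(fit)
  stats <- t(vapply(maps, function(m) {
    v <- m[roi_rows(roi), roi_cols(roi)]
    v <- v[is.finite(v)]
    if (!length(v)) c(mean = NaN, min = NaN, max = NaN, count_valid = 0)
    else c(mean = mean(v), min = min(v), max = max(v), count_valid = length(v))
  }, numeric(4)))
  if (stats["rho", "count_valid"] == 0) {
    warning("ROI contains no valid pixels; statistics are NaN")
  }
  structure(list(roi = roi, stats = as.data.frame(stats)), class = "roi_summary")
}

#' @export
print.roi_summary <- function(x, ...) {
  print(x$roi)
  print(round(x$stats, 4))
  invisible(x)
}

fmt_num <- function(v) {
  ifelse(is.finite(v), sprintf("%.17g", v), "NaN")
}

meta_header <- function(fit) {
  m <- fit$meta
  c("# gelcorr export",
    "# coordinates: 0-based pixel indices, origin at top-left, +x right (columns), +y down (rows)",
    sprintf("# variable\t%s", m$variable),
    sprintf("# variable_values\t%s", paste(fmt_num(m$values), collapse = ",")),
    sprintf("# normalization\t%s", m$scheme),
    sprintf("# test\t%s", m$test),
    sprintf("# n_samples\t%d", m$n),
    sprintf("# seed\t%d", m$seed),
    sprintf("# n_permutations\t%d", m$n_permutations),
    sprintf("# exhaustive\t%s", tolower(as.character(m$exhaustive))),
    sprintf("# min_valid\t%d", m$min_valid),
    sprintf("# significance\t%s", m$significance))
}

#' Export ROI pixel values and summary to a tab-delimited text file
#'
#' Layout: a `#`-prefixed header block carrying the analysis settings
#' (variable, normalization, test, n, seed, permutations), then one row per
#' ROI pixel with columns `x`, `y`, `rho`, `sigma_norm`, `p` and the product
#' maps, then the per-map summary rows. Numbers are written in full (17
#' significant digit) precision with `.` as the decimal separator; masked
#' pixels carry the literal `NaN`. The file re-imports with any generic
#' table reader.
#'
#' @param fit a `gel_result`.
#' @param roi a [gel_roi].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_roi_text <- function(fit, roi, path) {
  summ <- suppressWarnings(summarize_roi(fit, roi))
  maps <- result_maps(fit)
  lines <- meta_header(fit)
  lines <- c(lines, sprintf("# roi\tx0=%d\ty0=%d\twidth=%d\theight=%d",
                            roi$x0, roi$y0, roi$width, roi$height))
  cols <- c("x", "y", names(maps))
  lines <- c(lines, paste(cols, collapse = "\t"))
  for (yy in roi_rows(roi)) {
    for (xx in roi_cols(roi)) {
      vals <- vapply(maps, function(m) m[yy, xx], numeric(1))
      lines <- c(lines, paste(c(xx - 1, yy - 1, fmt_num(vals)), collapse = "\t"))
    }
  }
  lines <- c(lines, "# summary\tmap\tmean\tmin\tmax\tcount_valid")
  for (nm in rownames(summ$stats)) {
    s <- summ$stats[nm, ]
    lines <- c(lines, paste(c("# summary", nm, fmt_num(c(s$mean, s$min, s$max)),
                              sprintf("%d", s$count_valid)), collapse = "\t"))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Export one result map as a tab-delimited text grid
#'
#' Writes the settings header block followed by the `H x W` grid of values,
#' row-major (one image row per line), tab-delimited, full precision, `NaN`
#' for masked pixels. Re-importing reproduces the in-memory map exactly.
#'
#' @param fit a `gel_result`.
#' @param which map name: `"rho"`, `"sigma_norm"`, `"p"`, `"CS"`, `"CV"` or
#'   `"CSD"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_map_text <- function(fit, which, path) {
  maps <- result_maps(fit)
  if (!which %in% names(maps)) {
    gc_stop(sprintf("unknown map name '%s' (have: %s)", which,
                    paste(names(maps), collapse = ", ")), "gelcorr_param_error")
  }
  m <- maps[[which]]
  lines <- c(meta_header(fit),
             sprintf("# map\t%s", which),
             sprintf("# dimensions\theight=%d\twidth=%d", nrow(m), ncol(m)))
  body <- apply(m, 1, function(row) paste(fmt_num(row), collapse = "\t"))
  writeLines(c(lines, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read back a map exported with [export_map_text()]
#'
#' @param path exported file.
#' @return numeric matrix (`NaN` where masked).
#' @export
read_map_text <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE), as.numeric))
}

## map values to RGB via a diverging (signed, symmetric about 0) or
## sequential (unsigned) palette; NaN -> neutral gray
heatmap_rgb <- function(map, kind = c("signed", "unsigned")) {
  kind <- match.arg(kind)
  h <- nrow(map); w <- ncol(map)
  v <- as.vector(map)
  ok <- is.finite(v)
  if (kind == "signed") {
    ramp <- colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))  # blue-white-red
    mx <- if (any(ok)) max(abs(v[ok])) else 1
    if (mx == 0) mx <- 1
    u <- (v / mx + 1) / 2
  } else {
    ramp <- colorRamp(c("#FFFFD9", "#41B6C4", "#081D58"))  # light -> dark
    rng <- if (any(ok)) range(v[ok]) else c(0, 1)
    u <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0 + 0.5
  }
  u[!ok] <- 0.5
  cols <- ramp(pmin(pmax(u, 0), 1)) / 255
  cols[!ok, ] <- 0.5   # neutral gray for missing pixels
  array(cols, dim = c(h, w, 3))
}

#' Render a result map as an 8-bit RGB heat-map PNG
#'
#' Signed maps (rho and the products) use a diverging colormap symmetric
#' about zero (range `[-max|v|, +max|v|]`); unsigned maps (p, sigma) a
#' sequential one. `NaN` pixels render as neutral gray, distinct from both
#' extremes. Rendering is a pure read: stored map values are not modified.
#'
#' @param map numeric matrix.
#' @param kind `"signed"` or `"unsigned"`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(map, kind = c("signed", "unsigned"), path) {
  kind <- match.arg(kind)
  if (!is.matrix(map)) gc_stop("map must be a 2D matrix", "gelcorr_param_error")
  png::writePNG(heatmap_rgb(map, kind), path)
  invisible(path)
}
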