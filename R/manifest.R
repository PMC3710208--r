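#' Read a gel-stack manifest
#'
#' The manifest is a UTF-8, comma-delimited CSV with a header row and one row
#' per gel sample. Mandatory columns: `sample_id`, `signal_path`, `include`;
#' optional column `standard_path` (fluorescent standard image used for
#' alignment); every remaining column is an external variable (numeric, or a
#' category label with a natural ordering supplied later to
#' [encode_variable()]). `include` accepts `true`/`false`/`1`/`0`
#' case-insensitively and flags samples to keep in the analysis (excluded
#' samples are typically bad-quality gels).
#'
#' @param path manifest CSV path.
#' @return data.frame of class `gel_manifest`, one row per sample, with
#'   character columns `sample_id`, `signal_path`, `standard_path` (`NA` when
#'   absent), logical `include`, and the raw (character) variable columns;
#'   attribute `variables` holds the variable column names.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    gc_stop(sprintf("manifest file not found: %s", path), "gelcorr_io_error")
  }
  df <- read.csv(path, colClasses = "character", check.names = FALSE,
                 fileEncoding = "UTF-8")
  for (col in c("sample_id", "signal_path", "include")) {
    if (!col %in% names(df)) {
      gc_stop(sprintf("manifest is missing the mandatory column '%s'", col),
              "gelcorr_schema_error")
    }
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) {
    gc_stop(sprintf("duplicate sample_id in manifest: %s",
                    paste(unique(dup), collapse = ", ")),
            "gelcorr_id_error")
  }
  inc <- tolower(trimws(df$include))
  bad <- !inc %in% c("true", "false", "1", "0")
  if (any(bad)) {
    gc_stop(sprintf("unparseable include value(s): %s",
                    paste(unique(df$include[bad]), collapse = ", ")),
            "gelcorr_schema_error")
  }
  df$include <- inc %in% c("true", "1")
  if (!"standard_path" %in% names(df)) df$standard_path <- NA_character_
  vars <- setdiff(names(df), c("sample_id", "signal_path", "standard_path", "include"))
  if (length(vars) == 0) {
    gc_stop("manifest must contain at least one external-variable column",
            "gelcorr_schema_error")
  }
  # resolve image paths relative to the manifest location
  base <- dirname(normalizePath(path, mustWork = TRUE))
  attr(df, "variables") <- vars
  attr(df, "base_dir") <- base
  class(df) <- c("gel_manifest", "data.frame")
  df
}

#' Write a gel-stack manifest
#'
#' Inverse of [read_manifest()]: writes a canonicalized CSV (column order
#' `sample_id`, `signal_path`, `standard_path`, `include`, then variables;
#' `include` serialized as `true`/`false`). Reading the written file back
#' reproduces all fields.
#'
#' @param manifest a `gel_manifest` (or compatible data.frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)
  vars <- attr(manifest, "variables")
  if (is.null(vars)) {
    vars <- setdiff(names(df), c("sample_id", "signal_path", "standard_path", "include"))
  }
  if (!"standard_path" %in% names(df)) df$standard_path <- NA_character_
  out <- df[, c("sample_id", "signal_path", "standard_path", "include", vars)]
  out$include <- ifelse(out$include, "true", "false")
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "",
            fileEncoding = "UTF-8")
  invisible(path)
}

resolve_path <- function(p, base) {
  ifelse(is.na(p) | p == "" | grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
}

#' Load a gel image stack from manifest records
#'
#' Reads every included sample's image (signal by default, or the fluorescent
#' standard image when `use_standard = TRUE` — standards are used for
#' alignment so that protein expression itself does not bias the transform),
#' checks that all images share identical dimensions, and assembles a
#' [gel_stack] in manifest row order. Intensities keep their stored units
#' (8-bit 0..255, 16-bit 0..65535); the validity mask starts all-`TRUE`.
#'
#' @param manifest a `gel_manifest` from [read_manifest()].
#' @param use_standard load `standard_path` instead of `signal_path`.
#' @return a [gel_stack] of the included samples.
#' @export
load_stack <- function(manifest, use_standard = FALSE) {
  excluded <- manifest$sample_id[!manifest$include]
  if (length(excluded)) {
    gc_info("excluding samples: ", paste(excluded, collapse = ", "))
  }
  recs <- manifest[manifest$include, , drop = FALSE]
  if (nrow(recs) < 2) {
    gc_stop("fewer than 2 included samples", "gelcorr_stack_error")
  }
  base <- attr(manifest, "base_dir")
  if (is.null(base)) base <- "."
  paths <- if (use_standard) recs$standard_path else recs$signal_path
  if (use_standard && any(is.na(paths) | paths == "")) {
    gc_stop(sprintf("included sample(s) missing standard image: %s",
                    paste(recs$sample_id[is.na(paths) | paths == ""], collapse = ", ")),
            "gelcorr_io_error")
  }
  paths <- resolve_path(paths, base)
  imgs <- vector("list", nrow(recs))
  for (i in seq_along(paths)) {
    img <- read_gel_png(paths[i])
    if (i > 1 && !identical(dim(img), dim(imgs[[1]]))) {
      gc_stop(sprintf(
        "image dimension mismatch: %s is %dx%d but %s is %dx%d",
        paths[i], nrow(img), ncol(img),
        paths[1], nrow(imgs[[1]]), ncol(imgs[[1]])
      ), "gelcorr_dim_error")
    }
    imgs[[i]] <- img
  }
  gel_stack(imgs, recs$sample_id)
}

#' Encode an external variable as per-sample numbers
#'
#' Numeric columns pass through unchanged. Categorical columns require a
#' natural ordering: supply `category_order` and labels are mapped to their
#' 0-based rank in that order. Because the downstream statistic is the
#' Spearman rank correlation, any monotone encoding of ordered categories is
#' equivalent; consecutive integers are used as the canonical choice.
#'
#' @param manifest a `gel_manifest`.
#' @param name variable column name.
#' @param category_order optional character vector giving the ordering of
#'   category labels, smallest first. Required if any value is non-numeric.
#' @return an object of class `external_variable`: list with `name`, numeric
#'   `values` (one per included sample, manifest order), and `source_kind`
#'   (`"numeric"` or `"ordered_categorical"`).
#' @examples
#' \dontrun{
#' encode_variable(m, "hours")                      # numeric passthrough
#' encode_variable(m, "dose", c("low", "med", "high"))
#' }
#' @export
encode_variable <- function(manifest, name, category_order = NULL) {
  if (!name %in% names(manifest)) {
    gc_stop(sprintf("variable '%s' not found in manifest", name),
            "gelcorr_schema_error")
  }
  raw <- trimws(as.character(manifest[[name]][manifest$include]))
  if (any(is.na(raw) | raw == "")) {
    gc_stop(sprintf("variable '%s' has missing values for included samples", name),
            "gelcorr_encoding_error")
  }
  num <- suppressWarnings(as.numeric(raw))
  if (!anyNA(num) && is.null(category_order)) {
    values <- num
    kind <- "numeric"
  } else {
    if (is.null(category_order)) {
      gc_stop(sprintf(
        "variable '%s' has non-numeric values; supply category_order", name),
        "gelcorr_encoding_error")
    }
    idx <- match(raw, category_order)
    if (anyNA(idx)) {
      gc_stop(sprintf("label(s) absent from category_order for '%s': %s",
                      name, paste(unique(raw[is.na(idx)]), collapse = ", ")),
              "gelcorr_encoding_error")
    }
    values <- as.numeric(idx - 1L)  # 0-based rank
    kind <- "ordered_categorical"
  }
  if (length(unique(values)) < 2) {
    gc_stop(sprintf(
      "variable '%s' has fewer than 2 distinct values; correlation is undefined",
      name), "gelcorr_encoding_error")
  }
  structure(list(name = name, values = values, source_kind = kind),
            class = "external_variable")
}

#' @export
print.external_variable <- function(x, ...) {
  cat(sprintf("<external_variable> %s (%s): %s\n", x$name, x$source_kind,
              paste(signif(x$values, 6), collapse = ", ")))
  invisible(x)
}
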