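# Independent oracles and fixture builders shared across the suite.
# These deliberately avoid the package's own code paths: rank-then-Pearson
# via base cor(), permutation enumeration by direct recursion (not e1071).

# textbook Spearman: Pearson correlation of (mid)ranked values
spearman_oracle <- function(x, y) cor(rank(x), rank(y))

# all permutations of 1:n as a matrix, one per row, by recursion
perms_recursive <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_recursive(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# brute-force exhaustive two-sided permutation p for Spearman rho
brute_perm_p <- function(x, y) {
  P <- perms_recursive(length(y))
  r_obs <- spearman_oracle(x, y)
  r_null <- apply(P, 1, function(idx) spearman_oracle(x, y[idx]))
  mean(abs(r_null) >= abs(r_obs) - 1e-12)
}

# smooth synthetic image: sum of random Gaussian blobs on a background
smooth_image <- function(h = 64, w = 64, k = 6, seed = 1) {
  set.seed(seed)
  img <- matrix(20, h, w)
  gx <- 0:(w - 1); gy <- 0:(h - 1)
  for (i in seq_len(k)) {
    cx <- runif(1, 8, w - 9); cy <- runif(1, 8, h - 9)
    sx <- runif(1, 5, 10); sy <- runif(1, 5, 10)
    img <- img + runif(1, 50, 200) *
      outer(exp(-(gy - cy)^2 / (2 * sy^2)), exp(-(gx - cx)^2 / (2 * sx^2)))
  }
  img
}

# random-noise gel stack (no structure) for null behavior checks
noise_stack <- function(h, w, n, seed, offset = 100) {
  set.seed(seed)
  gel_stack(lapply(seq_len(n), function(i) {
    matrix(rnorm(h * w, offset, 10), h, w)
  }), paste0("s", seq_len(n)))
}

# write a small manifest + PNG images; returns the manifest path
write_tiny_dataset <- function(dir, values, hours, bits = 8L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(values)
  ids <- sprintf("g%02d", seq_len(n))
  for (i in seq_len(n)) {
    write_gel_png(values[[i]], file.path(dir, paste0(ids[i], ".png")), bits)
  }
  df <- data.frame(sample_id = ids,
                   signal_path = paste0(ids, ".png"),
                   include = "true",
                   hours = as.character(hours),
                   stringsAsFactors = FALSE)
  path <- file.path(dir, "manifest.csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
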