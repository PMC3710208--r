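test_that("spearman_rho matches hand-computed and textbook values", {
  expect_equal(spearman_rho(1:5, c(10, 20, 30, 40, 50)), 1)
  expect_equal(spearman_rho(1:5, c(50, 40, 30, 20, 10)), -1)
  # no ties: 1 - 6*sum(d^2)/(n(n^2-1)) with sum(d^2) = 4
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)), 0.8)
  # tie in x: Pearson on midranks, hand computation gives sqrt(0.9)
  expect_equal(spearman_rho(c(1, 2, 2, 3), 1:4), sqrt(0.9))

  expect_error(spearman_rho(c(1, 1, 1), 1:3), class = "gelcorr_undefined_error")
  expect_error(spearman_rho(1:2, 1:2), class = "gelcorr_param_error")
  expect_error(spearman_rho(1:4, c(1, 2, NA, 4)), class = "gelcorr_param_error")
})

test_that("spearman_rho agrees with an independent rank-then-Pearson oracle", {
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(4:9, 1)
    x <- rnorm(n)
    y <- if (rep %% 3 == 0) sample(x) else rnorm(n)  # occasional exact ties
    if (rep %% 5 == 0) x[2] <- x[1]
    expect_equal(spearman_rho(x, y), spearman_oracle(x, y), tolerance = 1e-14)
  }
})

test_that("correlation maps respect masks, min_valid and degenerate columns", {
  set.seed(2)
  h <- 6; w <- 5; n <- 5
  imgs <- lapply(1:n, function(i) matrix(rnorm(h * w, 50, 5), h, w))
  v <- c(1, 2, 3, 4, 5)
  for (i in 1:n) {
    imgs[[i]][2, 3] <- 10 + 2 * v[i]      # perfectly responsive pixel
    imgs[[i]][4, 4] <- 7                   # constant column
  }
  s <- gel_stack(imgs, paste0("s", 1:n))
  s$valid[5, 5, 1:3] <- FALSE              # only 2 of 5 samples valid

  cm <- correlation_map(s, v, min_valid = 4)
  expect_equal(cm$rho[2, 3], 1)
  expect_true(is.nan(cm$rho[4, 4]))        # constant -> undefined -> masked
  expect_false(cm$validity[4, 4])
  expect_true(is.nan(cm$rho[5, 5]))        # below min_valid
  expect_false(cm$validity[5, 5])

  # partial-validity pixel is computed from its valid subset only
  s$valid[5, 5, 1] <- TRUE                 # now 3 valid: samples 1, 4, 5
  cm3 <- correlation_map(s, v, min_valid = 3)
  keep <- c(1, 4, 5)
  expect_equal(cm3$rho[5, 5], spearman_oracle(s$data[5, 5, keep], v[keep]))

  expect_error(correlation_map(s, rep(1, n)), class = "gelcorr_param_error")
  expect_error(correlation_map(s, 1:3), class = "gelcorr_param_error")
})

test_that("t-test p-values match the closed form and its symmetries", {
  # rho = 0.8, n = 5: t = 0.8 * sqrt(3 / 0.36), df = 3
  t_expect <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(p_ttest(0.8, 5), 2 * pt(-t_expect, 3), tolerance = 1e-14)
  expect_equal(p_ttest(0.8, 5), 0.1041, tolerance = 1e-3)
  expect_equal(p_ttest(-0.8, 5), p_ttest(0.8, 5))      # two-sided symmetry
  expect_equal(p_ttest(0, 7), 1)
  expect_equal(p_ttest(1, 5), .Machine$double.xmin)    # clamp at |rho| = 1
  expect_error(p_ttest(0.5, 3), class = "gelcorr_param_error")
  expect_error(p_ttest(1.5, 5), class = "gelcorr_param_error")
})

test_that("exhaustive permutation p equals brute-force enumeration", {
  expect_equal(p_permutation(1:4, 1:4, test_config()), 2 / 24)
  expect_equal(p_permutation(1:5, c(2, 4, 6, 8, 10), test_config()), 2 / 120)

  set.seed(77)
  for (n in 4:6) {
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(p_permutation(x, y, test_config()), brute_perm_p(x, y))
    # ties travel with y: still exact vs brute force
    y_t <- y; y_t[2] <- y_t[1]
    expect_equal(p_permutation(x, y_t, test_config()), brute_perm_p(x, y_t))
  }
})

test_that("Monte Carlo permutation p is reproducible and near the exact value", {
  set.seed(15)
  x <- rnorm(7); y <- x + rnorm(7, 0, 1.5)
  cfg <- test_config("permutation", n_permutations = 999,
                     exhaustive_limit = 100, seed = 42)  # force Monte Carlo
  p1 <- p_permutation(x, y, cfg)
  p2 <- p_permutation(x, y, cfg)
  expect_identical(p1, p2)                                # same seed, same p
  p_exact <- p_permutation(x, y, test_config())           # 7! = 5040 exhaustive
  expect_lt(abs(p1 - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 999) + 2e-3)
})

test_that("null pixel correlations are centered and p-values honest", {
  s <- noise_stack(25, 40, 5, seed = 31)
  cm <- correlation_map(s, 1:5)
  expect_lt(abs(mean(cm$rho[cm$validity])), 0.05)   # 1000 null pixels
  expect_true(all(abs(cm$rho[cm$validity]) <= 1))
})

test_that("sigma_norm map scales the per-pixel sd into [0, 1] by the global max", {
  imgs <- lapply(1:4, function(i) matrix(0, 3, 3))
  for (i in 1:4) {
    imgs[[i]][1, 1] <- 5
    imgs[[i]][2, 2] <- c(1, 2, 3, 4)[i] * 2        # sd = 2*sd(1:4)
    imgs[[i]][3, 3] <- c(1, 2, 3, 4)[i] * 4        # sd = 4*sd(1:4)
  }
  s <- gel_stack(imgs, paste0("s", 1:4))
  m <- sigma_norm_map(s)
  expect_equal(m[1, 1], 0)                          # constant column
  expect_equal(m[3, 3], 1)                          # global max by construction
  expect_equal(m[2, 2], 0.5)                        # direct ratio of sds
  expect_true(all(m[is.finite(m)] >= 0 & m[is.finite(m)] <= 1))

  # coefficient-of-variation alternative: sd / |mean|, scaled by its own max
  cvm <- sigma_norm_map(s, kind = "cv")
  sd_ratio <- sd(c(2, 4, 6, 8)) / mean(c(2, 4, 6, 8))    # pixel [2,2]
  sd_ratio2 <- sd(c(4, 8, 12, 16)) / mean(c(4, 8, 12, 16))
  expect_equal(cvm[2, 2] / cvm[3, 3], sd_ratio / sd_ratio2)  # equal CVs -> 1
  expect_true(is.nan(cvm[1, 2]))                    # zero-mean pixels masked
})

test_that("product maps combine factors with absorbing zeros and NaN", {
  maps <- list(rho = matrix(c(1, 0.5, NaN, -1), 2, 2),
               sigma_norm = matrix(c(0.5, 0, 1, 1), 2, 2),
               p = matrix(c(1e-9, 0.5, 0.2, 1e-9), 2, 2))
  csd <- product_map(maps, c("rho", "significance", "sigma_norm"))
  expect_equal(csd[1, 1], 1 * (1 - 1e-9) * 0.5)
  expect_equal(csd[2, 1], 0)                        # absorbing zero
  expect_true(is.nan(csd[1, 2]))                    # NaN propagates
  expect_equal(csd[2, 2], -1 * (1 - 1e-9) * 1)      # signed product

  cv <- product_map(maps, c("rho", "sigma_norm"))
  expect_equal(cv[1, 1], 0.5)
  nl <- product_map(maps, c("rho", "significance"), "neg_log10_p")
  expect_equal(nl[1, 1], -log10(1e-9))
  expect_error(product_map(maps, c("rho", "bogus")), class = "gelcorr_param_error")
})

test_that("the correlation-times-variance product suppresses flat responders", {
  # two perfectly correlated pixels; one barely moves in intensity
  v <- 1:5
  imgs <- lapply(v, function(vi) {
    m <- matrix(100, 4, 4)
    m[1, 1] <- 100 + 40 * vi        # strong responder
    m[2, 2] <- 100 + 0.1 * vi       # rho = 1 but negligible variance
    m
  })
  fit <- gel_correlate(gel_stack(imgs, paste0("s", v)), v, scheme = "none",
                       cfg = test_config("permutation", seed = 1), min_valid = 5)
  expect_equal(fit$rho[1, 1], 1)
  expect_equal(fit$rho[2, 2], 1)
  expect_gt(fit$products$CV[1, 1], 10 * fit$products$CV[2, 2])
})

test_that("rank statistics are invariant to monotone covariate transforms", {
  spec <- preset_p53_timecourse(seed = 7, misaligned = FALSE)
  spec$h <- 48; spec$w <- 96
  gen <- generate_stack(spec)
  v <- spec$covariate_values
  cfg <- test_config("permutation", seed = 5)
  fit <- gel_correlate(gen$stack, v, scheme = "median", cfg = cfg)
  fit_sq <- gel_correlate(gen$stack, v^2, scheme = "median", cfg = cfg)
  expect_identical(fit$rho, fit_sq$rho)
  expect_identical(fit$p, fit_sq$p)

  # negating the covariate negates rho and preserves p (two-sided)
  fit_neg <- gel_correlate(gen$stack, -v, scheme = "median", cfg = cfg)
  ok <- fit$validity
  expect_identical(fit_neg$rho[ok], -fit$rho[ok])
  expect_identical(fit_neg$p, fit$p)

  # t-test route shows the same symmetries
  cfg_t <- test_config("t_test")
  ft <- gel_correlate(gen$stack, v, scheme = "median", cfg = cfg_t)
  ft_neg <- gel_correlate(gen$stack, -v, scheme = "median", cfg = cfg_t)
  expect_identical(ft_neg$p, ft$p)
})

test_that("gel_correlate records complete provenance metadata", {
  s <- noise_stack(6, 6, 5, seed = 4)
  fit <- gel_correlate(s, c(0, 2, 4, 6, 8), scheme = "median",
                       cfg = test_config("permutation", seed = 99))
  m <- fit$meta
  expect_equal(m$n, 5)
  expect_equal(m$seed, 99)
  expect_equal(m$scheme, "median")
  expect_equal(m$test, "permutation")
  expect_true(m$exhaustive)
  expect_equal(m$n_permutations, 120)
  expect_equal(m$min_valid, 5)
  expect_equal(sort(names(fit$products)), c("CS", "CSD", "CV"))
  # q-value extension: BH is monotone in p and bounded by 1
  q <- adjust_pvalues(fit)
  sel <- is.finite(q)
  expect_true(all(q[sel] >= fit$p[sel] - 1e-15 & q[sel] <= 1))
})
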