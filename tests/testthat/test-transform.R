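test_that("identity and integer-translation transforms are exact", {
  img <- smooth_image(32, 40, seed = 7)
  for (interp in c("nearest", "bilinear")) {
    r <- apply_transform(img, identity_transform(), interp)
    expect_identical(r$image, img)
    expect_true(all(r$valid))
  }
  # pure translation +3 columns, nearest: content shifts right, left edge invalid
  r <- apply_transform(img, similarity_transform(0, 1, 3, 0), "nearest")
  expect_equal(r$image[, 4:40], img[, 1:37])
  expect_false(any(r$valid[, 1:3]))
  expect_true(all(r$valid[, 4:40]))
  expect_true(all(r$image[, 1:3] == 0))
})

test_that("90-degree rotation of a square image matches the array-rotation oracle", {
  set.seed(5)
  n <- 11
  m <- matrix(runif(n * n, 0, 100), n, n)
  r <- apply_transform(m, similarity_transform(90), "bilinear")
  oracle <- t(m)[n:1, ]        # counter-clockwise array rotation (display sense)
  expect_lt(max(abs(r$image - oracle)), 1e-9)
  expect_true(all(r$valid))
})

test_that("transform parameter validation rejects bad inputs", {
  expect_error(similarity_transform(0, 0, 0, 0), class = "gelcorr_param_error")
  expect_error(similarity_transform(0, -2, 0, 0), class = "gelcorr_param_error")
  expect_error(similarity_transform(NA, 1, 0, 0), class = "gelcorr_param_error")
  expect_error(similarity_transform(0, 1, Inf, 0), class = "gelcorr_param_error")
})

test_that("inversion is exact in parameters and near-exact on images", {
  expect_equal(invert(identity_transform()), identity_transform())
  expect_equal(invert(similarity_transform(0, 2, 0, 0)),
               similarity_transform(0, 0.5, 0, 0))

  img <- smooth_image(64, 64, seed = 11)
  rng <- diff(range(img))
  for (t in list(similarity_transform(7, 1.05, 3.3, -2.1),
                 similarity_transform(-12, 0.93, -4.7, 1.9),
                 similarity_transform(3, 1.0, 0.5, 0.5))) {
    fwd <- apply_transform(img, t, "bilinear")
    back <- apply_transform(fwd$image, invert(t), "bilinear")
    # jointly valid region: the back-transform must interpolate only pixels
    # whose bilinear neighbors were all inside the forward footprint
    mask_back <- apply_transform(fwd$valid * 1, invert(t), "bilinear")
    both <- back$valid & mask_back$valid & (mask_back$image > 1 - 1e-9)
    expect_gt(mean(both), 0.5)
    expect_lt(max(abs(back$image[both] - img[both])), 0.02 * rng)
  }
})

test_that("composition matches sequential application", {
  img <- smooth_image(48, 48, seed = 3)
  t1 <- similarity_transform(10, 1.1, 2, -1)
  t2 <- similarity_transform(-4, 0.95, -1.5, 2.5)
  step1 <- apply_transform(img, t1, "bilinear")
  seq2 <- apply_transform(step1$image, t2, "bilinear")
  once <- apply_transform(img, compose(t2, t1), "bilinear")
  # exclude pixels whose second-pass neighbors fell outside t1's footprint
  carried <- apply_transform(step1$valid * 1, t2, "bilinear")
  both <- seq2$valid & once$valid & carried$valid & (carried$image > 1 - 1e-9)
  # double interpolation vs single: allow a small smoothing tolerance
  expect_lt(max(abs(seq2$image[both] - once$image[both])), 0.03 * diff(range(img)))

  # integer translations with nearest-neighbor compose exactly
  ta <- similarity_transform(0, 1, 3, 1)
  tb <- similarity_transform(0, 1, -1, 2)
  seq_n <- apply_transform(apply_transform(img, ta, "nearest")$image, tb, "nearest")
  once_n <- apply_transform(img, compose(tb, ta), "nearest")
  both_n <- seq_n$valid & once_n$valid
  expect_identical(seq_n$image[both_n], once_n$image[both_n])
})

test_that("landmark estimation recovers exact and least-squares transforms", {
  pts <- cbind(c(10, 50, 10, 50), c(12, 12, 48, 48))
  hw <- c(64, 64)
  # identity and pure translation fits are exact
  suppressMessages(est0 <- estimate_from_landmarks(pts, pts, hw))
  expect_equal(unclass(est0), unclass(identity_transform()), tolerance = 1e-12)
  suppressMessages(
    est_t <- estimate_from_landmarks(pts, cbind(pts[, 1] + 5, pts[, 2] - 2), hw)
  )
  expect_equal(c(est_t$rotation_deg, est_t$scale, est_t$tx, est_t$ty),
               c(0, 1, 5, -2), tolerance = 1e-9)

  # forward-generated rotation 30 deg + scale 1.5 about center is recovered
  dst <- t(apply(pts, 1, function(p) {
    # independent forward model: rotate about center in display coordinates
    th <- 30 * pi / 180; c0 <- (hw - 1) / 2
    dx <- p[1] - c0[2]; dy <- p[2] - c0[1]
    c(1.5 * (cos(th) * dx + sin(th) * dy) + c0[2],
      1.5 * (-sin(th) * dx + cos(th) * dy) + c0[1])
  }))
  suppressMessages(est <- estimate_from_landmarks(pts, dst, hw))
  expect_equal(c(est$rotation_deg, est$scale, est$tx, est$ty),
               c(30, 1.5, 0, 0), tolerance = 1e-6)

  expect_error(estimate_from_landmarks(pts[1, , drop = FALSE],
                                       pts[1, , drop = FALSE], hw),
               class = "gelcorr_estimation_error")
  same <- matrix(5, 3, 2)
  expect_error(estimate_from_landmarks(same, pts[1:3, ], hw),
               class = "gelcorr_estimation_error")
})

test_that("landmark fit is least-squares optimal against a local grid search", {
  set.seed(9)
  pts <- cbind(runif(6, 5, 55), runif(6, 5, 55))
  z <- exp(-1i * 12 * pi / 180) * 1.2   # rotation 12 deg, scale 1.2
  cc <- complex(real = 31.5, imaginary = 31.5)
  src_c <- complex(real = pts[, 1], imaginary = pts[, 2])
  dst_c <- z * (src_c - cc) + cc + complex(real = 3, imaginary = -2)
  dst <- cbind(Re(dst_c), Im(dst_c)) + matrix(rnorm(12, 0, 0.5), 6, 2)
  suppressMessages(fit <- estimate_from_landmarks(pts, dst, c(64, 64)))
  rms <- function(t) {
    a <- t$scale * exp(-1i * t$rotation_deg * pi / 180)
    pred <- a * (src_c - cc) + cc + complex(real = t$tx, imaginary = t$ty)
    sqrt(mean(Mod(complex(real = dst[, 1], imaginary = dst[, 2]) - pred)^2))
  }
  best <- rms(fit)
  for (dr in c(-0.5, 0, 0.5)) for (ds in c(-0.02, 0, 0.02))
    for (dx in c(-0.5, 0, 0.5)) for (dy in c(-0.5, 0, 0.5)) {
      alt <- similarity_transform(fit$rotation_deg + dr, fit$scale + ds,
                                  fit$tx + dx, fit$ty + dy)
      expect_gte(rms(alt), best - 1e-9)
    }
})

test_that("align_stack realigns a known shift and tracks footprints", {
  img <- smooth_image(48, 48, seed = 21)
  shift <- similarity_transform(0, 1, 5, -3)
  moved <- apply_transform(img, shift, "bilinear")
  stack <- gel_stack(list(img, moved$image), c("ref", "mov"))
  stack$valid[, , 2] <- moved$valid

  al <- alignment_set("ref", list(mov = invert(shift)))
  out <- align_stack(stack, al, "bilinear")
  expect_identical(out$data[, , 1], img)          # reference untouched
  both <- out$valid[, , 1] & out$valid[, , 2]
  expect_lt(max(abs(out$data[, , 2][both] - img[both])), 0.02 * diff(range(img)))

  # all-identity alignment leaves the stack unchanged
  out_id <- align_stack(stack, alignment_set("ref", list()), "bilinear")
  expect_identical(out_id$data, stack$data)
  expect_identical(out_id$valid, stack$valid)

  # a transform pushing the image fully off-canvas invalidates it
  gone <- alignment_set("ref", list(mov = similarity_transform(0, 1, 500, 0)))
  out_gone <- align_stack(stack, gone, "nearest")
  expect_false(any(out_gone$valid[, , 2]))

  expect_error(align_stack(stack, alignment_set("ref", list(zz = identity_transform()))),
               "zz", class = "gelcorr_id_error")
})

test_that("alignment sets roundtrip through JSON and CSV", {
  dir <- withr::local_tempdir()
  al <- alignment_set("a", list(a = identity_transform(),
                                b = similarity_transform(3.5, 1.02, -2.25, 4)))
  jf <- file.path(dir, "al.json")
  write_alignment(al, jf)
  al2 <- read_alignment(jf)
  expect_equal(al2$reference_id, "a")
  expect_equal(al2$transforms$b, al$transforms$b)

  cf <- file.path(dir, "al.csv")
  writeLines(c("sample_id,rotation_deg,scale,tx,ty",
               "a,0,1,0,0", "b,3.5,1.02,-2.25,4"), cf)
  al3 <- read_alignment(cf)
  expect_equal(al3$reference_id, "a")
  expect_equal(al3$transforms$b, al$transforms$b)

  expect_error(alignment_set("b", al$transforms), class = "gelcorr_param_error")
})

test_that("overlay blending is exact at the alpha extremes and midpoint", {
  a <- matrix(c(0, 5, 10, 20), 2, 2)
  b <- matrix(c(100, 50, 0, 100), 2, 2)
  sc <- function(m) (m - min(m)) / diff(range(m))
  expect_equal(render_overlay(a, b, 0), sc(a))
  expect_equal(render_overlay(a, b, 1), sc(b))
  expect_equal(render_overlay(matrix(0, 2, 2), matrix(7, 2, 2), 0.5),
               matrix(0, 2, 2))   # constant inputs scale to zero
  expect_equal(render_overlay(a, b, 0.5), 0.5 * sc(a) + 0.5 * sc(b))
  expect_error(render_overlay(a, matrix(0, 3, 2), 0.5), class = "gelcorr_dim_error")
  expect_error(render_overlay(a, b, 1.5), class = "gelcorr_param_error")
})
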