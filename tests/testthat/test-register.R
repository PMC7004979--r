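test_that("mutual information matches closed forms", {
  # 50/50 binary image: MI(X, X) = H(X) = 1 bit
  img <- matrix(rep(c(0, 255), each = 8), 4, 4)
  expect_equal(mutual_information(img, img), 1, tolerance = 1e-6)
  # independence from a constant image
  expect_equal(mutual_information(img, matrix(5, 4, 4)), 0)
  # hand-computed joint histogram {(0,0):8, (0,1):4, (1,1):4} over 16 px:
  # MI = .5 log2(4/3) + .25 log2(2/3) + .25 log2(2) = 0.311278 bits; with
  # intensities exactly on bin centres the linear binning reduces to hard
  # counting, so the value is exact
  f <- matrix(c(rep(0, 12), rep(1, 4)), 4, 4)
  m <- matrix(c(rep(0, 8), rep(1, 8)), 4, 4)
  expect_equal(mutual_information(f, m, bins = 2), 0.311278124459, tolerance = 1e-9)
  expect_error(mutual_information(matrix(0, 2, 2), matrix(0, 3, 3)),
               "identical dimensions")
})

test_that("mutual information is symmetric and maximal on self", {
  set.seed(4)
  a <- textured_image(48, seed = 4)
  b <- textured_image(48, seed = 5)
  expect_lt(abs(mutual_information(a, b) - mutual_information(b, a)), 1e-12)
  expect_gte(mutual_information(a, a), mutual_information(a, b))
  expect_gte(mutual_information(a, b), 0)
})

test_that("affine transforms compose, invert and map points exactly", {
  ctr <- c(31.5, 31.5)
  T1 <- affine2d(1.02, 0.01, -0.02, 0.98, 3, -2, ctr[1], ctr[2])
  idn <- affine2d(cx = ctr[1], cy = ctr[2])
  expect_equal(affine_mu(compose_affine(T1, idn)), affine_mu(T1),
               tolerance = 1e-14)
  # two pure translations sum
  Ta <- affine2d(tx = 2, ty = 5, cx = ctr[1], cy = ctr[2])
  Tb <- affine2d(tx = -7, ty = 1, cx = ctr[1], cy = ctr[2])
  expect_equal(unname(affine_mu(compose_affine(Ta, Tb))[5:6]), c(-5, 6),
               tolerance = 1e-14)
  # compose with the inverse gives the identity
  expect_equal(unname(affine_mu(compose_affine(T1, invert_affine(T1)))),
               c(1, 0, 0, 1, 0, 0), tolerance = 1e-10)
  # closed-form point mapping: T(x) = A(x - c) + t + c
  p <- c(10, 20)
  expect_equal(as.vector(transform_points(T1, rbind(p))),
               as.vector(T1$A %*% (p - ctr) + T1$t + ctr), tolerance = 1e-14)
  # composition across different centres is still algebraically consistent
  T2 <- affine2d(1, 0.005, 0, 1, 1, 0, 10, 12)
  pts <- rbind(c(0, 0), c(40, 17))
  expect_equal(transform_points(compose_affine(T1, T2), pts),
               transform_points(T1, transform_points(T2, pts)),
               tolerance = 1e-10)
})

test_that("apply_affine is exact where bilinear interpolation is exact", {
  img <- textured_image(64, seed = 31)
  ctr <- image_center(img)
  idn <- affine2d(cx = ctr[1], cy = ctr[2])
  expect_identical(apply_affine(img, idn), img)
  # pure integer translation: exact shifted copy on the interior
  Tt <- affine2d(tx = 5, ty = -3, cx = ctr[1], cy = ctr[2])
  w <- apply_affine(img, Tt)
  expect_identical(w[4:61, 1:59], img[1:58, 6:64])
  # warp round trip on a smooth image: mean abs diff < 2% of range
  Ts <- affine2d(1.03, 0.01, -0.005, 0.97, 2.5, -1.5, ctr[1], ctr[2])
  sm <- amst:::gauss_blur_cpp(img, 2)
  back <- apply_affine(apply_affine(sm, Ts), invert_affine(Ts))
  interior <- 17:48
  err <- mean(abs(back[interior, interior] - sm[interior, interior]))
  expect_lt(err, 0.02 * diff(range(sm)))
})

test_that("registration recovers identity and known warps", {
  fixed <- textured_image(128, sigma = 4, seed = 55)
  ctr <- image_center(fixed)
  cfg <- amst_config()
  expect_equal(cfg$iterations, 200L)  # the workflow's standard setting
  r0 <- register_affine(fixed, fixed, config = cfg)
  expect_false(r0$rejected)
  expect_lt(corner_displacement(r0$transform,
                                affine2d(cx = ctr[1], cy = ctr[2]), 128, 128),
            0.2)
  # scale 1.02 about the centre
  Ttrue <- affine2d(1.02, 0, 0, 1.02, 0, 0, ctr[1], ctr[2])
  moving <- apply_affine(fixed, invert_affine(Ttrue))
  r1 <- register_affine(fixed, moving, config = cfg)
  expect_lt(corner_displacement(r1$transform, Ttrue, 128, 128), 0.5)
  # the optimum did not decrease the metric
  expect_gte(r1$metric, r1$mi_initial)
})

test_that("registration agrees with an exhaustive MI grid-search oracle", {
  fixed <- textured_image(128, sigma = 4, seed = 56)
  ctr <- image_center(fixed)
  Ttrue <- affine2d(1.02, 0, 0, 1.02, 0, 0, ctr[1], ctr[2])
  moving <- apply_affine(fixed, invert_affine(Ttrue))
  # independent route: brute-force scan of isotropic scale only (the
  # interpolation of the re-warp biases the grid optimum by a couple of
  # grid steps, so both routes are held to the same absolute tolerance)
  scales <- seq(0.98, 1.06, by = 0.002)
  mi <- vapply(scales, function(s) {
    mutual_information(fixed,
                       apply_affine(moving,
                                    affine2d(s, 0, 0, s, 0, 0,
                                             ctr[1], ctr[2])))
  }, numeric(1))
  best <- scales[which.max(mi)]
  expect_lt(abs(best - 1.02), 0.005)
  r <- register_affine(fixed, moving)
  expect_lt(abs(unname(affine_mu(r$transform)["a11"]) - 1.02), 0.005)
  expect_lt(abs(unname(affine_mu(r$transform)["a22"]) - 1.02), 0.005)
  expect_lt(abs(unname(affine_mu(r$transform)["a11"]) - best), 0.01)
})

test_that("coarse translation initialisation finds large offsets", {
  fixed <- textured_image(128, sigma = 4, seed = 57)
  ctr <- image_center(fixed)
  moving <- apply_affine(fixed, affine2d(tx = 12, ty = 5,
                                         cx = ctr[1], cy = ctr[2]))
  # moving content displaced by (-12, -5); the init equals that
  # displacement and maps directly onto the transform's t
  o <- coarse_translation_init(fixed, moving)
  expect_lt(abs(o$dx - (-12)), 0.5)
  expect_lt(abs(o$dy - (-5)), 0.5)
  expect_equal(eval(formals(coarse_translation_init)$presmooth_sigma), 1.6)
  r <- register_affine(fixed, moving, init = o)
  expect_lt(corner_displacement(r$transform,
                                affine2d(tx = -12, ty = -5,
                                         cx = ctr[1], cy = ctr[2]),
                                128, 128), 0.5)
})

test_that("implausible results are rejected with a translation-only fallback", {
  cfg <- amst_config(det_bounds = c(0.999999, 1.000001))
  fixed <- textured_image(64, seed = 58)
  Ttrue <- affine2d(1.03, 0, 0, 1.03, 0, 0, 31.5, 31.5)
  moving <- apply_affine(fixed, invert_affine(Ttrue))
  r <- register_affine(fixed, moving, init = c(1, 2), config = cfg)
  expect_true(r$rejected)
  expect_equal(unname(affine_mu(r$transform)),
               c(1, 0, 0, 1, 1, 2), tolerance = 1e-12)
})

test_that("affine warping agrees with an independent implementation", {
  skip_if_not_installed("EBImage")
  img <- amst:::gauss_blur_cpp(textured_image(96, seed = 91), 2)
  # our backward warp about c = 0: output(x) = input(A x + t); the same
  # geometry in EBImage is the forward transform B = A^-1, b = -A^-1 t
  A <- matrix(c(1.03, 0.01, -0.02, 0.97), 2, 2, byrow = TRUE)
  tt <- c(2.5, -1.5)
  ours <- apply_affine(img, affine2d(A[1, 1], A[1, 2], A[2, 1], A[2, 2],
                                     tt[1], tt[2], 0, 0))
  B <- solve(A)
  m <- rbind(t(B), as.vector(-B %*% tt))
  theirs <- t(EBImage::imageData(
    EBImage::affine(EBImage::Image(t(img)), m, filter = "bilinear",
                    bg.col = 0)))
  interior <- 20:77
  expect_lt(mean(abs(ours[interior, interior] - theirs[interior, interior])),
            0.01 * diff(range(img)))
  # pure translation: both implementations are exact, so they agree exactly
  oT <- apply_affine(img, affine2d(tx = 4, ty = -2))
  mT <- rbind(diag(2), c(-4, 2))
  tT <- t(EBImage::imageData(
    EBImage::affine(EBImage::Image(t(img)), mT, filter = "bilinear",
                    bg.col = 0)))
  expect_equal(oT[interior, interior], tT[interior, interior],
               tolerance = 1e-12)
})

test_that("transforms serialize to JSON and back", {
  ts <- list(affine2d(1.01, 0, 0.002, 0.99, 1.5, -2, 63.5, 63.5),
             affine2d(cx = 63.5, cy = 63.5))
  f <- withr::local_tempfile(fileext = ".json")
  write_transforms(ts, f)
  r <- read_transforms(f)
  for (k in 1:2) {
    expect_equal(affine_mu(r[[k]]), affine_mu(ts[[k]]), tolerance = 1e-12)
    expect_equal(r[[k]]$c, ts[[k]]$c, tolerance = 1e-12)
  }
})
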