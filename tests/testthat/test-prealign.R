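ctr128 <- c(63.5, 63.5)

test_that("template matching self-matches exactly and refines subpixel shifts", {
  img <- textured_image(128)
  tpl <- img[51:70, 101:120]  # top-left (x = 100, y = 50), 0-based
  m <- match_template(img, tpl, c(100, 50), 10)
  expect_lt(sqrt(m$dx^2 + m$dy^2), 0.1)
  expect_equal(m$score, 1, tolerance = 1e-10)
  # content shifted by (+3.25, -1.5): T(x) = x + t with t = -shift
  shifted <- apply_affine(img, affine2d(tx = -3.25, ty = 1.5,
                                        cx = ctr128[1], cy = ctr128[2]))
  m2 <- match_template(shifted, tpl, c(100, 50), 12)
  expect_lt(abs(m2$dx - 3.25), 0.5)
  expect_lt(abs(m2$dy - (-1.5)), 0.5)
  expect_gt(m2$score, 0.9)
})

test_that("degenerate templates and windows are rejected", {
  img <- textured_image(64)
  expect_error(match_template(img, matrix(7, 10, 10), c(20, 20), 5),
               "degenerate template")
  flat <- matrix(3, 64, 64)
  tpl <- img[11:20, 11:20]
  expect_error(match_template(flat, tpl, c(20, 20), 5), "degenerate")
})

test_that("NCC peak ties break towards the search centre", {
  # periodic image: equal peaks one period apart
  img <- matrix(0, 40, 60)
  img[, c(10, 25, 40) + 1] <- 255
  tpl <- img[11:20, 21:31]  # top-left (x = 20, y = 10), contains stripe 25
  m <- match_template(img, tpl, c(20, 10), 15)
  expect_equal(c(m$dx, m$dy), c(0, 0))
})

test_that("pairwise translation estimation recovers identity and shifts", {
  img <- textured_image(128, seed = 11)
  o0 <- estimate_translation_pair(img, img)
  expect_lt(sqrt(o0$dx^2 + o0$dy^2), 0.05)
  # integer shift (7, -4)
  mov <- apply_affine(img, affine2d(tx = -7, ty = 4,
                                    cx = ctr128[1], cy = ctr128[2]))
  o <- estimate_translation_pair(img, mov)
  expect_lt(abs(o$dx - 7), 0.5)
  expect_lt(abs(o$dy - (-4)), 0.5)
  # the presmoothing default is the standard 1.6 px
  expect_equal(eval(formals(estimate_translation_pair)$presmooth_sigma), 1.6)
  expect_error(estimate_translation_pair(matrix(1, 32, 32), matrix(1, 32, 32)),
               "unalignable")
})

test_that("TM pre-alignment anchors the fiducial across a drifting stack", {
  spec <- phantom_spec(Z = 10, H = 128, W = 128, n_fiducials = 1,
                       scale_jitter = 0, shear_jitter = 0,
                       translation_jitter = 0, drift = c(0.5, 0),
                       outlier_period = 100, noise_sigma = 2, seed = 5)
  vol <- generate_phantom_volume(spec)
  dst <- distort_stack(vol, spec)
  fp <- fiducial_patch(vol, spec)
  pa <- align_tm(dst$stack, fp$patch, fp$position, search_radius = 15)
  # recovered offsets must undo the drift: offset of slice k is
  # +drift * (k - 1) within 0.5 px
  for (k in 1:10) {
    expect_lt(abs(pa$offsets[k, 1] - 0.5 * (k - 1)), 0.5)
    expect_lt(abs(pa$offsets[k, 2]), 0.5)
  }
  # zero-drift stack: all offsets near zero
  spec0 <- phantom_spec(Z = 6, H = 128, W = 128, n_fiducials = 1,
                        scale_jitter = 0, shear_jitter = 0,
                        translation_jitter = 0, drift = c(0, 0),
                        outlier_period = 100, noise_sigma = 2, seed = 6)
  vol0 <- generate_phantom_volume(spec0)
  dst0 <- distort_stack(vol0, spec0)
  fp0 <- fiducial_patch(vol0, spec0)
  pa0 <- align_tm(dst0$stack, fp0$patch, fp0$position, search_radius = 10)
  expect_true(all(abs(pa0$offsets) < 0.25))
})

test_that("a destroyed fiducial is flagged low-confidence, neighbours unaffected", {
  spec <- phantom_spec(Z = 8, H = 128, W = 128, n_fiducials = 1,
                       scale_jitter = 0, shear_jitter = 0,
                       translation_jitter = 1, drift = c(0, 0),
                       outlier_period = 100, noise_sigma = 2, seed = 8)
  vol <- generate_phantom_volume(spec)
  dst <- distort_stack(vol, spec)
  fp <- fiducial_patch(vol, spec)
  clean <- align_tm(dst$stack, fp$patch, fp$position, search_radius = 12)
  broken <- dst$stack
  broken$slices[[5]][1:48, ] <- 0  # wipe the band (and fiducial) of slice 5
  expect_warning(
    pa <- align_tm(broken, fp$patch, fp$position, search_radius = 12),
    "low-confidence.*5")
  expect_true(pa$low_confidence[5])
  expect_false(any(pa$low_confidence[-5]))
  expect_equal(pa$offsets[-5, ], clean$offsets[-5, ], tolerance = 1e-12)
  # the interpolated offset stays within the neighbours' range
  expect_true(pa$offsets[5, 1] >= min(pa$offsets[c(4, 6), 1]) - 1e-9)
  expect_true(pa$offsets[5, 1] <= max(pa$offsets[c(4, 6), 1]) + 1e-9)
})

test_that("feature pre-alignment leaves sub-half-pixel pairwise residuals", {
  spec <- phantom_spec(Z = 12, H = 128, W = 128, scale_jitter = 0,
                       shear_jitter = 0, translation_jitter = 5,
                       drift = c(0.3, 0.1), outlier_period = 100,
                       noise_sigma = 3, seed = 13)
  vol <- generate_phantom_volume(spec)
  dst <- distort_stack(vol, spec)
  pa <- align_feature(dst$stack)
  expect_equal(unname(pa$offsets[1, ]), c(0, 0))
  aligned <- apply_prealignment(dst$stack, pa)
  res <- vapply(2:12, function(k) {
    o <- estimate_translation_pair(aligned$slices[[k - 1]],
                                   aligned$slices[[k]])
    sqrt(o$dx^2 + o$dy^2)
  }, numeric(1))
  expect_lt(sqrt(mean(res^2)), 0.5)
  # an already-aligned stack yields offsets ~0
  pa2 <- align_feature(vol)
  expect_true(all(abs(pa2$offsets) < 0.5))
})

test_that("offset application is exact for integer and half-pixel shifts", {
  s <- random_stack(z = 2, h = 20, w = 20, seed = 21)
  # zero offsets: identity
  pa0 <- amst:::new_pre_alignment(matrix(0, 2, 2), "tm")
  expect_identical(apply_prealignment(s, pa0)$slices, s$slices)
  # integer offset (3, 0): exact shifted copy on the interior
  pa3 <- amst:::new_pre_alignment(rbind(c(3, 0), c(0, 0)), "tm")
  sh <- apply_prealignment(s, pa3)
  expect_identical(sh$slices[[1]][, 4:20], s$slices[[1]][, 1:17])
  expect_true(all(sh$slices[[1]][, 1:3] == 0))
  # half-pixel offset: interior equals the average of horizontal neighbours
  pah <- amst:::new_pre_alignment(rbind(c(0.5, 0), c(0, 0)), "tm")
  hf <- apply_prealignment(s, pah)
  expected <- (s$slices[[1]][, 1:19] + s$slices[[1]][, 2:20]) / 2
  expect_equal(hf$slices[[1]][, 2:20], expected, tolerance = 1e-12)
})

test_that("offsets serialize to CSV and JSON and back", {
  pa <- amst:::new_pre_alignment(rbind(c(1.5, -2), c(0, 0.25)), "tm",
                                 scores = c(0.9, 0.8))
  for (ext in c(".csv", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_offsets(pa, f)
    r <- read_offsets(f)
    expect_equal(r$offsets, pa$offsets, tolerance = 1e-12)
    expect_equal(r$scores, pa$scores)
  }
})
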