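#' Specification for a synthetic FIB-SEM-like phantom
#'
#' Defines the geometry, texture, distortion and noise of a seeded
#' synthetic stack emulating the failure modes of real FIB-SEM
#' acquisitions: per-slice affine pixel-size jitter (scale/shear),
#' periodic outlier slices with amplified distortion (the auto-focus /
#' auto-stigmation signature), slow cumulative drift, a flat surface band
#' carrying fiducial marks, and additive imaging noise.
#'
#' The defaults are the package's standard validation conditions: a
#' 64-slice 256x256 stack at 5 nm/px, scale jitter of 1 percent, shear
#' jitter 0.005, translation jitter of 3 px, drift of (0.2, 0) px/slice,
#' every 10th slice an outlier with 4x amplitude, and Gaussian noise with
#' sigma 5 grey levels on the 8-bit scale.
#'
#' @param Z,H,W stack dimensions (slices, rows, columns).
#' @param pixel_size_nm,slice_thickness_nm physical metadata.
#' @param band_top rows of dark embedding material above the surface
#'   band, giving the band room to move under distortion.
#' @param band_rows thickness of the flat surface ("platinum") band, in
#'   rows.
#' @param n_fiducials number of X-shaped fiducial marks in the band.
#' @param texture_sigma_xy,texture_sigma_z Gaussian correlation lengths of
#'   the membranous texture, in px and slices.
#' @param scale_jitter,shear_jitter,translation_jitter half-widths of the
#'   uniform per-slice distortion draws (scale about 1, shear about 0,
#'   translation in px).
#' @param outlier_period every `outlier_period`-th slice is an outlier
#'   (>= 2); `outlier_multiplier` scales its distortion amplitudes.
#' @param drift per-slice cumulative drift `(dx, dy)` in px.
#' @param noise_sigma additive Gaussian noise sigma (grey levels).
#' @param background fill value for pixels warped in from outside.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(Z = 64L, H = 256L, W = 256L, pixel_size_nm = 5,
                         slice_thickness_nm = 8, band_top = 16L,
                         band_rows = 24L,
                         n_fiducials = 3L, texture_sigma_xy = 5,
                         texture_sigma_z = 8, scale_jitter = 0.01,
                         shear_jitter = 0.005, translation_jitter = 3,
                         outlier_period = 10L, outlier_multiplier = 4,
                         drift = c(0.2, 0), noise_sigma = 5,
                         background = 0, seed = 0L) {
  stopifnot(Z >= 1, H >= 32, W >= 32, pixel_size_nm > 0,
            slice_thickness_nm > 0, band_top >= 0, band_rows >= 16,
            band_top + band_rows < H / 2,
            n_fiducials >= 1, outlier_period >= 2,
            all(is.finite(c(scale_jitter, shear_jitter, translation_jitter,
                            outlier_multiplier, drift, noise_sigma))))
  structure(list(Z = as.integer(Z), H = as.integer(H), W = as.integer(W),
                 pixel_size_nm = pixel_size_nm,
                 slice_thickness_nm = slice_thickness_nm,
                 band_top = as.integer(band_top),
                 band_rows = as.integer(band_rows),
                 n_fiducials = as.integer(n_fiducials),
                 texture_sigma_xy = texture_sigma_xy,
                 texture_sigma_z = texture_sigma_z,
                 scale_jitter = scale_jitter, shear_jitter = shear_jitter,
                 translation_jitter = translation_jitter,
                 outlier_period = as.integer(outlier_period),
                 outlier_multiplier = outlier_multiplier,
                 drift = drift, noise_sigma = noise_sigma,
                 background = background, seed = as.integer(seed)),
            class = "phantom_spec")
}

# clipped-window Gaussian smoothing matrix along z (columns renormalized)
zsmooth_matrix <- function(Z, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  K <- matrix(0, Z, Z)
  for (z in seq_len(Z)) {
    zz <- max(1L, z - r):min(Z, z + r)
    w <- exp(-0.5 * (zz - z)^2 / sigma^2)
    K[zz, z] <- w / sum(w)
  }
  K
}

#' Generate the undistorted phantom volume
#'
#' Builds a z-coherent textured volume: a band-limited 3-D Gaussian random
#' field whose zero level set is turned into bright membrane-like ridges,
#' under a flat dark surface band carrying bright X-shaped fiducial marks
#' at fixed `(x, y)` across all slices. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return An [image_stack()] (`uint8`, values 0-255).
#' @export
generate_phantom_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  H <- spec$H; W <- spec$W; Z <- spec$Z
  noise <- array(stats::rnorm(H * W * Z), c(H, W, Z))
  for (z in seq_len(Z))
    noise[, , z] <- gauss_blur_cpp(noise[, , z], spec$texture_sigma_xy)
  field <- matrix(noise, H * W, Z) %*% zsmooth_matrix(Z, spec$texture_sigma_z)
  field <- field / stats::sd(field)
  membrane <- exp(-(field / 0.3)^2)
  shading <- 1 / (1 + exp(-3 * field))
  img <- 30 + 150 * membrane + 40 * shading
  dim(img) <- c(H, W, Z)
  # dark embedding margin, then flat surface band with fiducial marks,
  # all constant across z
  top <- matrix(12, spec$band_top + spec$band_rows, W)
  top[spec$band_top + seq_len(spec$band_rows), ] <- 60
  marks <- fiducial_geometry(spec)
  for (i in seq_len(nrow(marks$px)))
    top[marks$px[i, "y"] + 1, marks$px[i, "x"] + 1] <- 230
  slices <- lapply(seq_len(Z), function(z) {
    s <- img[, , z]
    s[seq_len(nrow(top)), ] <- top
    round(pmin(pmax(s, 0), 255))
  })
  image_stack(slices, spec$pixel_size_nm, spec$slice_thickness_nm, "uint8")
}

# 0-based pixel coordinates of all fiducial mark pixels plus mark centres
fiducial_geometry <- function(spec) {
  my <- spec$band_top + spec$band_rows %/% 2
  r <- min(7L, spec$band_rows %/% 2 - 3L)
  centers <- round(spec$W * seq_len(spec$n_fiducials) /
                     (spec$n_fiducials + 1))
  px <- NULL
  for (mx in centers) {
    for (t in -r:r) {
      # X shape, 2 px thick
      px <- rbind(px,
                  c(x = mx + t, y = my + t), c(x = mx + t + 1, y = my + t),
                  c(x = mx - t, y = my + t), c(x = mx - t + 1, y = my + t))
    }
  }
  px <- px[px[, "x"] >= 0 & px[, "x"] < spec$W, , drop = FALSE]
  list(px = px, centers = cbind(x = centers, y = rep(my, length(centers))),
       radius = r)
}

#' Fiducial template patch for TM pre-alignment
#'
#' Cuts the patch around the first fiducial mark from the undistorted
#' volume together with its true top-left position, for use with
#' [align_tm()]. Because the mark's true position is known by
#' construction, anchoring the pre-alignment at this position places
#' every slice in the undistorted frame.
#'
#' @param volume the output of [generate_phantom_volume()].
#' @param spec the [phantom_spec()] used to generate it.
#' @param margin pixels of context around the mark.
#' @return A list: `patch` (matrix) and `position` (`(x, y)`, 0-based
#'   top-left).
#' @export
fiducial_patch <- function(volume, spec, margin = 4L) {
  geo <- fiducial_geometry(spec)
  cx <- geo$centers[1, "x"]; cy <- geo$centers[1, "y"]
  r <- geo$radius + margin
  x0 <- max(0L, cx - r); y0 <- max(0L, cy - r)
  x1 <- min(spec$W - 1L, cx + r)
  y1 <- min(spec$band_top + spec$band_rows - 1L, cy + r)
  list(patch = volume$slices[[1]][(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)],
       position = c(x = x0, y = y0))
}

#' Distort a phantom volume with known per-slice transforms
#'
#' Resamples each slice through a random affine distortion (scale and
#' shear jitter about identity; translations = jitter + cumulative drift)
#' and adds Gaussian noise after warping (so registration must cope with
#' non-identical intensities). Every `outlier_period`-th slice is an
#' outlier: its scale, shear and translation components take the full
#' `outlier_multiplier`-amplified amplitude with random signs, so outlier
#' distortions always exceed the nominal jitter bound — the invariant
#' that distinguishes flagged slices. The exact transforms applied are
#' recorded:
#' `transforms` holds the *alignment* transforms (the inverse of each
#' applied distortion — what a perfect registration should recover) and
#' `distortions` the applied warps themselves.
#'
#' @param volume an [image_stack()] from [generate_phantom_volume()].
#' @param spec the corresponding [phantom_spec()].
#' @return A list: `stack` (the distorted [image_stack()]) and `truth`
#'   (class `ground_truth_distortion`).
#' @export
distort_stack <- function(volume, spec) {
  stopifnot(inherits(volume, "image_stack"), inherits(spec, "phantom_spec"))
  d <- stack_dim(volume)
  Z <- unname(d["Z"]); H <- unname(d["H"]); W <- unname(d["W"])
  ctr <- image_center(volume$slices[[1]])
  set.seed(spec$seed + 1L)
  draws <- matrix(stats::runif(Z * 6, -1, 1), Z, 6)
  outlier <- (seq_len(Z) %% spec$outlier_period) == 0L
  distortions <- vector("list", Z)
  transforms <- vector("list", Z)
  slices <- vector("list", Z)
  for (z in seq_len(Z)) {
    # outlier slices get the full amplified amplitude with random sign, so
    # their distortion always exceeds the nominal jitter bound (the
    # invariant that makes the outlier flag meaningful); ordinary slices
    # draw uniformly within the bound
    dz <- if (outlier[z]) sign(draws[z, ]) * spec$outlier_multiplier
          else draws[z, ]
    sx <- 1 + dz[1] * spec$scale_jitter
    sy <- 1 + dz[2] * spec$scale_jitter
    hx <- dz[3] * spec$shear_jitter
    hy <- dz[4] * spec$shear_jitter
    tj <- dz[5:6] * spec$translation_jitter
    tD <- tj + spec$drift * (z - 1)
    D <- affine2d(sx, hx, hy, sy, tD[1], tD[2], ctr[1], ctr[2])
    distortions[[z]] <- D
    transforms[[z]] <- invert_affine(D)
    warped <- apply_affine(volume$slices[[z]], D, fill = spec$background)
    if (spec$noise_sigma > 0)
      warped <- warped + matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W)
    slices[[z]] <- round(pmin(pmax(warped, 0), 255))
  }
  stack <- with_slices(volume, slices)
  truth <- structure(list(transforms = transforms, distortions = distortions,
                          outlier = outlier,
                          drift = outer(seq_len(Z) - 1, spec$drift),
                          noise_sigma = spec$noise_sigma, seed = spec$seed,
                          dim = c(Z = Z, H = H, W = W),
                          pixel_size_nm = volume$pixel_size_xy_nm),
                     class = "ground_truth_distortion")
  list(stack = stack, truth = truth)
}

#' @rdname distort_stack
#' @param x a `ground_truth_distortion`.
#' @param ... ignored.
#' @export
print.ground_truth_distortion <- function(x, ...) {
  cat(sprintf("<ground_truth_distortion> %d slices (%d outliers), seed %d\n",
              x$dim["Z"], sum(x$outlier), x$seed))
  invisible(x)
}

#' Corner-displacement error between recovered and true transforms
#'
#' For each slice, the mean over the four image corners of the Euclidean
#' distance between the recovered and the true transform's mapping of that
#' corner, reported in pixels and in nanometers. This is the oracle metric
#' for parameter-recovery tests on synthetic stacks.
#'
#' @param truth a `ground_truth_distortion` from [distort_stack()].
#' @param recovered list of [affine2d()] transforms, one per slice
#'   (e.g. `coef`-level output of [amst()]), or a `pre_alignment` (whose
#'   offsets are interpreted as translation-only transforms).
#' @return A data frame: `slice`, `error_px`, `error_nm`, `outlier`.
#' @export
recovery_error <- function(truth, recovered) {
  stopifnot(inherits(truth, "ground_truth_distortion"))
  Z <- truth$dim["Z"]; H <- truth$dim["H"]; W <- truth$dim["W"]
  ctr <- c((W - 1) / 2, (H - 1) / 2)
  if (inherits(recovered, "pre_alignment"))
    recovered <- lapply(seq_len(nrow(recovered$offsets)), function(k)
      affine2d(tx = -recovered$offsets[k, 1], ty = -recovered$offsets[k, 2],
               cx = ctr[1], cy = ctr[2]))
  if (length(recovered) != Z)
    stop("expected ", Z, " recovered transforms, got ", length(recovered))
  corners <- rbind(c(0, 0), c(W - 1, 0), c(0, H - 1), c(W - 1, H - 1))
  err <- vapply(seq_len(Z), function(z) {
    pr <- transform_points(recovered[[z]], corners)
    pt <- transform_points(truth$transforms[[z]], corners)
    mean(sqrt(rowSums((pr - pt)^2)))
  }, numeric(1))
  data.frame(slice = seq_len(Z), error_px = err,
             error_nm = err * truth$pixel_size_nm, outlier = truth$outlier)
}

# 1-D shift between two profiles by bounded-range normalized
# cross-correlation with quadratic sub-sample refinement. Returns the
# displacement of `cur` relative to `ref` (cur[i] ~= ref[i - s]). The
# bounded search (no wrap-around) keeps repeated structure in the profile
# (e.g. the two edges of a surface band) from aliasing onto each other.
profile_shift <- function(ref, cur, max_shift = 10L) {
  n <- length(ref)
  shifts <- (-max_shift):max_shift
  sc <- vapply(shifts, function(s) {
    i_cur <- max(1L, 1L + s):min(n, n + s)
    a <- ref[i_cur - s]; b <- cur[i_cur]
    a <- a - mean(a); b <- b - mean(b)
    den <- sqrt(sum(a * a) * sum(b * b))
    if (den == 0) -Inf else sum(a * b) / den
  }, numeric(1))
  k <- which.max(sc)
  sub <- if (k > 1 && k < length(sc) && all(is.finite(sc[(k - 1):(k + 1)])))
    quad_refine(sc[k - 1], sc[k], sc[k + 1]) else 0
  shifts[k] + sub
}

#' Per-slice vertical position of the sample surface
#'
#' Estimates, for each slice, the vertical (y) displacement of the top
#' part of the image relative to the first slice by 1-D correlation of
#' row-mean profiles. On phantoms with a flat surface band this measures
#' whether the band stays a straight horizontal line through the stack:
#' its range over z is the surface drift.
#'
#' @param stack an [image_stack()].
#' @param top_rows number of top rows forming the profile (default: the
#'   top third of the image). Choose a window that covers the surface
#'   band and its edges but little of the specimen texture — texture
#'   decorrelates along z and would dilute the correlation.
#' @param max_shift search range in px for the per-slice displacement.
#' @return Numeric vector of per-slice y-displacements in px (slice 1 = 0).
#' @export
surface_profile <- function(stack, top_rows = NULL, max_shift = 10L) {
  stopifnot(inherits(stack, "image_stack"))
  d <- stack_dim(stack)
  if (is.null(top_rows)) top_rows <- max(16L, d["H"] %/% 3)
  top_rows <- min(top_rows, d["H"])
  prof <- function(s) rowMeans(s)[seq_len(top_rows)]
  ref <- prof(stack$slices[[1]])
  vapply(stack$slices, function(s) profile_shift(ref, prof(s), max_shift),
         numeric(1))
}
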