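# Shared fixtures, all generated in code under fixed seeds.

# smooth textured image (band-limited noise), values roughly in [0, 255]
textured_image <- function(h = 128, w = h, sigma = 3, seed = 42) {
  set.seed(seed)
  img <- amst:::gauss_blur_cpp(matrix(rnorm(h * w), h, w), sigma)
  img <- (img - min(img)) / diff(range(img))
  round(255 * img)
}

# small uint8 stack of independent random slices
random_stack <- function(z = 4, h = 16, w = 16, seed = 7) {
  set.seed(seed)
  image_stack(replicate(z, matrix(sample(0:255, h * w, TRUE), h, w),
                        simplify = FALSE))
}

# mean corner displacement (px) between two transforms on an H x W canvas
corner_displacement <- function(T1, T2, h, w) {
  corners <- rbind(c(0, 0), c(w - 1, 0), c(0, h - 1), c(w - 1, h - 1))
  mean(sqrt(rowSums((transform_points(T1, corners) -
                       transform_points(T2, corners))^2)))
}

# brute-force z-median oracle: per-voxel sort, clipped window, lower median
zmedian_oracle <- function(arr, window) {
  storage.mode(arr) <- "double"
  d <- dim(arr)
  hw <- window %/% 2
  out <- arr
  for (z in seq_len(d[3])) {
    zz <- max(1, z - hw):min(d[3], z + hw)
    out[, , z] <- apply(arr[, , zz, drop = FALSE], c(1, 2), function(v) {
      sort(v)[(length(v) - 1) %/% 2 + 1]
    })
  }
  out
}
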