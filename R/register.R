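#' 2-D affine transform about a fixed centre
#'
#' Represents the mapping \eqn{T_\mu(x) = A(x - c) + t + c} with
#' \eqn{A = \{a_{11}, a_{12}; a_{21}, a_{22}\}}, translation
#' \eqn{t = (t_x, t_y)} in pixels and rotation centre `c` (by convention
#' the image centre `((W-1)/2, (H-1)/2)` in 0-based pixel coordinates).
#' The parameter vector is \eqn{\mu = (a_{11},a_{12},a_{21},a_{22},t_x,t_y)}.
#'
#' @param a11,a12,a21,a22 matrix entries of `A`.
#' @param tx,ty translation in pixels.
#' @param cx,cy rotation centre in pixels.
#' @return An object of class `affine2d`.
#' @examples
#' affine2d(tx = 3, ty = -1, cx = 127.5, cy = 127.5)
#' @export
affine2d <- function(a11 = 1, a12 = 0, a21 = 0, a22 = 1, tx = 0, ty = 0,
                     cx = 0, cy = 0) {
  mu <- c(a11 = a11, a12 = a12, a21 = a21, a22 = a22, tx = tx, ty = ty)
  if (!all(is.finite(mu)) || !all(is.finite(c(cx, cy))))
    stop("affine parameters must be finite")
  structure(list(A = matrix(c(a11, a21, a12, a22), 2, 2),
                 t = c(tx, ty), c = c(cx, cy)),
            class = "affine2d")
}

#' @rdname affine2d
#' @param T an `affine2d`.
#' @export
affine_mu <- function(T) {
  stopifnot(inherits(T, "affine2d"))
  c(a11 = T$A[1, 1], a12 = T$A[1, 2], a21 = T$A[2, 1], a22 = T$A[2, 2],
    tx = T$t[1], ty = T$t[2])
}

#' @rdname affine2d
#' @export
image_center <- function(img) {
  d <- dim(img)
  c(cx = (d[2] - 1) / 2, cy = (d[1] - 1) / 2)
}

#' @rdname affine2d
#' @param x an `affine2d`.
#' @param ... ignored.
#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d> T(x) = A(x - c) + t + c\n")
  cat(sprintf("  A = [%8.5f %8.5f; %8.5f %8.5f]   det %.5f\n",
              x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2], det(x$A)))
  cat(sprintf("  t = (%.4f, %.4f) px,  c = (%.2f, %.2f)\n",
              x$t[1], x$t[2], x$c[1], x$c[2]))
  invisible(x)
}

#' Apply an affine transform to points
#'
#' @param T an [affine2d()].
#' @param pts numeric matrix with columns `(x, y)` in pixels.
#' @return Transformed points, same shape.
#' @export
transform_points <- function(T, pts) {
  stopifnot(inherits(T, "affine2d"))
  pts <- rbind(pts)
  sweep(sweep(pts, 2, T$c) %*% t(T$A), 2, T$t + T$c, "+")
}

# (M, b) form: T(x) = M x + b
affine_Mb <- function(T) list(M = T$A, b = T$t + T$c - T$A %*% T$c)

affine_from_Mb <- function(M, b, cx, cy) {
  t <- as.vector(b) - c(cx, cy) + as.vector(M %*% c(cx, cy))
  affine2d(M[1, 1], M[1, 2], M[2, 1], M[2, 2], t[1], t[2], cx, cy)
}

#' Compose two affine transforms
#'
#' Returns the transform equivalent to applying `inner` first, then
#' `outer`: `T(x) = outer(inner(x))`, re-expressed about `outer`'s centre.
#' Composing the transforms (rather than the images) is what allows the
#' pipeline to resample the raw data exactly once.
#'
#' @param outer,inner [affine2d()] objects.
#' @return An [affine2d()].
#' @export
compose_affine <- function(outer, inner) {
  o <- affine_Mb(outer); i <- affine_Mb(inner)
  affine_from_Mb(o$M %*% i$M, o$M %*% i$b + o$b, outer$c[1], outer$c[2])
}

#' @rdname compose_affine
#' @param T an [affine2d()] to invert.
#' @export
invert_affine <- function(T) {
  mb <- affine_Mb(T)
  Mi <- solve(mb$M)
  affine_from_Mb(Mi, -Mi %*% mb$b, T$c[1], T$c[2])
}

#' Resample an image through an affine transform
#'
#' Backward warping: `output(x)` is the bilinear sample of `img` at
#' `T(x)`; samples falling outside the image domain are set to `fill`.
#' Exactly one resampling pass.
#'
#' @param img numeric matrix (rows = y, cols = x).
#' @param T an [affine2d()].
#' @param fill background value for out-of-domain samples.
#' @return A numeric matrix of the same size.
#' @export
apply_affine <- function(img, T, fill = 0) {
  stopifnot(is.matrix(img), inherits(T, "affine2d"))
  warp_affine_cpp(img, unname(affine_mu(T)), T$c[1], T$c[2], fill)
}

#' Mutual information between two images
#'
#' MI of the joint intensity histogram in bits. Intensities of each image
#' are min-max scaled to the bin range; each pixel spreads its count over
#' the neighbouring bins with linear (partial-volume) weights, so values
#' that land exactly on bin centres reproduce the plain hard-binned
#' histogram. Symmetric in its arguments and non-negative.
#'
#' @param fixed,moving numeric matrices of identical size.
#' @param bins number of histogram bins per axis (default 32).
#' @return MI in bits (a single non-negative number).
#' @examples
#' img <- matrix(rep(c(0, 255), each = 8), 4, 4)
#' mutual_information(img, img)  # = H(X) = 1 bit for a 50/50 binary image
#' @export
mutual_information <- function(fixed, moving, bins = 32L) {
  if (!is.matrix(fixed) || !is.matrix(moving) ||
      !identical(dim(fixed), dim(moving)))
    stop("'fixed' and 'moving' must be matrices of identical dimensions")
  stopifnot(bins >= 2)
  fr <- range(fixed); mr <- range(moving)
  mi_affine_cpp(fixed, moving, c(1, 0, 0, 1, 0, 0), 0, 0, as.integer(bins),
                fr[1], fr[2], mr[1], mr[2])
}

#' Registration configuration
#'
#' Tuning parameters for [register_affine()] and [amst()]. Defaults follow
#' the workflow's standard settings: 200 gradient-descent iterations, MI
#' with a 32-bin joint histogram, a 3-level Gaussian pyramid, an optional
#' coarse translation initialisation after Gaussian smoothing with
#' sigma = 1.6 px, and a z-median template window of 15 slices.
#'
#' @param iterations maximum optimizer iterations per pyramid level.
#' @param bins joint-histogram bins for the MI metric.
#' @param pyramid_levels Gaussian pyramid levels (coarse to fine).
#' @param coarse_init run a phase-correlation translation step before the
#'   affine optimisation.
#' @param presmooth_sigma Gaussian sigma (px) for translation estimation.
#' @param median_window z-median template window (odd number of slices).
#' @param fill background value for out-of-canvas pixels.
#' @param tm_threshold NCC peak score below which a template match is
#'   flagged low-confidence and replaced by neighbour interpolation.
#' @param det_bounds accepted range for `det(A)` of a final transform.
#' @param init_step,step_tol,grad_eps optimizer internals: initial step in
#'   normalized parameter units, convergence step threshold, and
#'   finite-difference epsilon.
#' @return A list of class `amst_config`.
#' @export
amst_config <- function(iterations = 200L, bins = 32L, pyramid_levels = 3L,
                        coarse_init = TRUE, presmooth_sigma = 1.6,
                        median_window = 15L, fill = 0, tm_threshold = 0.5,
                        det_bounds = c(0.5, 2), init_step = 0.02,
                        step_tol = 1e-5, grad_eps = 1e-3) {
  stopifnot(iterations >= 1, bins >= 8, pyramid_levels >= 1,
            presmooth_sigma >= 0, length(det_bounds) == 2)
  if (median_window %% 2 == 0)
    stop("'median_window' must be odd")
  structure(list(iterations = as.integer(iterations), bins = as.integer(bins),
                 pyramid_levels = as.integer(pyramid_levels),
                 coarse_init = isTRUE(coarse_init),
                 presmooth_sigma = presmooth_sigma,
                 median_window = as.integer(median_window), fill = fill,
                 tm_threshold = tm_threshold, det_bounds = det_bounds,
                 init_step = init_step, step_tol = step_tol,
                 grad_eps = grad_eps),
            class = "amst_config")
}

#' Coarse translation initialisation
#'
#' Estimates the translation bringing `moving` close to `fixed` before the
#' affine refinement, by phase correlation after Gaussian smoothing
#' (sigma = 1.6 px by default). The returned offset is the displacement of
#' `moving` relative to `fixed` and maps directly onto the initial
#' translation `t` of the affine transform.
#'
#' @inheritParams estimate_translation_pair
#' @return A [translation_offset()].
#' @export
coarse_translation_init <- function(fixed, moving, presmooth_sigma = 1.6) {
  estimate_translation_pair(fixed, moving, presmooth_sigma)
}

# blur + subsample one pyramid level; factor 1 returns the input
pyramid_level <- function(img, factor) {
  if (factor == 1) return(img)
  sm <- gauss_blur_cpp(img, factor / 2)
  sm[seq(1, nrow(img), by = factor), seq(1, ncol(img), by = factor),
     drop = FALSE]
}

#' Affine registration by mutual-information maximisation
#'
#' Registers `moving` (a raw slice) to `fixed` (its template slice) with
#' the full affine model of [affine2d()], maximising mutual information by
#' adaptive-step gradient descent with finite-difference gradients on
#' normalized parameters (translations scaled by the image extent), over a
#' Gaussian pyramid from coarse to fine. The optimisation starts at
#' `A = I`, `t = init` (or 0) and `c` = image centre; parameters are
#' unconstrained during optimisation, and the final result is rejected
#' (with `rejected = TRUE` and a translation-only fallback transform) only
#' if `det(A)` leaves the configured sanity bounds or any parameter is
#' non-finite.
#'
#' @param fixed,moving numeric matrices of identical size.
#' @param init optional [translation_offset()] (or numeric `(dx, dy)`)
#'   initial translation, typically from [coarse_translation_init()].
#' @param config an [amst_config()].
#' @return A list of class `affine_registration`: `transform`
#'   ([affine2d()]), `metric` (final MI, bits), `mi_initial` (MI before
#'   registration), `rejected`, and `iterations` used per pyramid level.
#' @export
register_affine <- function(fixed, moving, init = NULL,
                            config = amst_config()) {
  if (!is.matrix(fixed) || !is.matrix(moving) ||
      !identical(dim(fixed), dim(moving)))
    stop("'fixed' and 'moving' must be matrices of identical dimensions")
  H <- nrow(fixed); W <- ncol(fixed)
  ctr <- image_center(fixed)
  t0 <- c(0, 0)
  if (!is.null(init)) {
    t0 <- if (inherits(init, "translation_offset")) c(init$dx, init$dy)
          else as.numeric(init)[1:2]
    if (!all(is.finite(t0))) stop("'init' must be finite")
  }
  E <- max(H, W)
  # normalized parameters: (a11, a12, a21, a22, tx/E, ty/E)
  p <- c(1, 0, 0, 1, t0[1] / E, t0[2] / E)
  mi_initial <- mutual_information(fixed, moving, config$bins)

  nlev <- config$pyramid_levels
  nlev <- max(1L, min(nlev, floor(log2(min(H, W) / 16)) + 1L))
  factors <- 2L^((nlev - 1L):0L)
  iters_used <- integer(0)
  metric <- NA_real_
  for (f in factors) {
    ff <- pyramid_level(fixed, f)
    mf <- pyramid_level(moving, f)
    fr <- range(ff); mr <- range(mf)
    cxy <- ctr / f
    obj <- function(q) {
      mu <- c(q[1:4], q[5] * E / f, q[6] * E / f)
      mi_affine_cpp(ff, mf, mu, cxy[1], cxy[2], config$bins,
                    fr[1], fr[2], mr[1], mr[2])
    }
    cur <- obj(p)
    step <- config$init_step
    eps <- config$grad_eps
    it <- 0L
    while (it < config$iterations) {
      it <- it + 1L
      g <- numeric(6)
      for (j in 1:6) {
        pp <- p; pp[j] <- pp[j] + eps
        pm <- p; pm[j] <- pm[j] - eps
        g[j] <- (obj(pp) - obj(pm)) / (2 * eps)
      }
      gn <- sqrt(sum(g * g))
      if (gn < 1e-12) break
      cand <- p + step * g / gn
      val <- obj(cand)
      if (val > cur + 1e-12) {
        p <- cand; cur <- val
        step <- min(step * 1.25, 10 * config$init_step)
      } else {
        step <- step / 2
      }
      if (step < config$step_tol) break
    }
    iters_used <- c(iters_used, it)
    metric <- cur
  }
  mu <- c(p[1:4], p[5] * E, p[6] * E)
  A <- matrix(c(mu[1], mu[3], mu[2], mu[4]), 2, 2)
  dA <- det(A)
  rejected <- !all(is.finite(mu)) || dA < config$det_bounds[1] ||
    dA > config$det_bounds[2]
  transform <- if (rejected) {
    affine2d(tx = t0[1], ty = t0[2], cx = ctr[1], cy = ctr[2])
  } else {
    affine2d(mu[1], mu[2], mu[3], mu[4], mu[5], mu[6], ctr[1], ctr[2])
  }
  structure(list(transform = transform, metric = metric,
                 mi_initial = mi_initial, rejected = rejected,
                 iterations = iters_used),
            class = "affine_registration")
}

#' @rdname register_affine
#' @param x an `affine_registration`.
#' @param ... ignored.
#' @export
print.affine_registration <- function(x, ...) {
  cat(sprintf("<affine_registration> MI %.4f -> %.4f bits%s\n",
              x$mi_initial, x$metric,
              if (x$rejected) "  [REJECTED: translation-only fallback]" else ""))
  print(x$transform)
  invisible(x)
}

#' Serialize per-slice transforms to JSON
#'
#' Writes the parameter vector `mu`, the centre `c` and optional per-slice
#' diagnostics for each transform, readable back with
#' [read_transforms()].
#'
#' @param transforms list of [affine2d()] objects.
#' @param path output JSON file.
#' @param diagnostics optional data frame of per-slice diagnostics.
#' @return Invisibly, `path`.
#' @export
write_transforms <- function(transforms, path, diagnostics = NULL) {
  rec <- lapply(seq_along(transforms), function(k) {
    T <- transforms[[k]]
    out <- list(slice = k, mu = unname(affine_mu(T)), center = unname(T$c))
    if (!is.null(diagnostics)) out$diagnostics <- as.list(diagnostics[k, ])
    out
  })
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transforms
#' @export
read_transforms <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(rec)), function(k) {
    mu <- unlist(rec$mu[k]); ce <- unlist(rec$center[k])
    affine2d(mu[1], mu[2], mu[3], mu[4], mu[5], mu[6], ce[1], ce[2])
  })
}
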