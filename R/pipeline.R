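#' Align a stack to its median-smoothed template
#'
#' The full three-step workflow. (i) A translation-only pre-alignment is
#' computed, by fiducial template matching (`prealign = "tm"`) or by
#' slice-to-slice phase correlation (`prealign = "feature"`). (ii) The
#' pre-aligned stack is median-filtered along z only, yielding the
#' template dataset. (iii) Each *raw* slice is registered to its template
#' slice with an affine transform by mutual-information maximisation,
#' initialised from the pre-alignment offset (optionally refined by a
#' coarse translation step), and resampled exactly once through the
#' single composed transform.
#'
#' Each slice depends only on the template, so slice processing is
#' order-independent and embarrassingly parallel (`cores`). Slices whose
#' affine result fails the determinant sanity check fall back to their
#' translation-only initialisation, with a warning; the median template
#' makes single fallbacks benign.
#'
#' @param raw an [image_stack()] of raw (unaligned) slices.
#' @param prealign `"tm"` (fiducial template matching; requires
#'   `template` and `template_position`) or `"feature"`.
#' @param template,template_position,reference_slice,search_radius
#'   passed to [align_tm()] when `prealign = "tm"`.
#' @param config an [amst_config()].
#' @param cores worker processes for the per-slice registration stage.
#' @param keep_template retain the template stack in the result.
#' @return An object of class `amst`: `aligned` (the re-aligned
#'   [image_stack()]), `transforms` (per-slice [affine2d()]),
#'   `prealignment`, `diagnostics` (per-slice MI before/after,
#'   determinant, fallback flag), `config`, and optionally `template`.
#'   Methods: `print`, `summary`, `coef` (Z x 6 matrix of parameter
#'   vectors mu), `plot`, `residuals` (displacement-error trace of the
#'   aligned stack).
#' @seealso [evaluate_alignment()], [recovery_error()]
#' @export
amst <- function(raw, prealign = c("tm", "feature"), template = NULL,
                 template_position = NULL, reference_slice = NULL,
                 search_radius = NULL, config = amst_config(), cores = 1L,
                 keep_template = FALSE) {
  stopifnot(inherits(raw, "image_stack"), inherits(config, "amst_config"))
  prealign <- match.arg(prealign)
  Z <- n_slices(raw)
  pa <- if (prealign == "tm") {
    if (is.null(template) || is.null(template_position))
      stop("'tm' pre-alignment requires 'template' and 'template_position'")
    if (is.null(search_radius)) search_radius <- 2 * max(dim(template))
    align_tm(raw, template, template_position, reference_slice,
             search_radius, config$tm_threshold)
  } else {
    align_feature(raw, config$presmooth_sigma)
  }
  prealigned <- apply_prealignment(raw, pa, config$fill)
  tmpl <- compute_template(prealigned, config$median_window)

  register_one <- function(z) {
    fixed <- tmpl$slices[[z]]
    moving <- raw$slices[[z]]
    t0 <- -pa$offsets[z, ]
    if (config$coarse_init) {
      shifted <- prealigned$slices[[z]]
      d <- tryCatch(
        estimate_translation_pair(fixed, shifted, config$presmooth_sigma),
        error = function(e) NULL)
      if (!is.null(d)) t0 <- t0 + c(d$dx, d$dy)
    }
    reg <- register_affine(fixed, moving, init = t0, config = config)
    list(z = z, transform = reg$transform,
         aligned = apply_affine(moving, reg$transform, config$fill),
         mi_before = reg$mi_initial, mi_after = reg$metric,
         det = det(reg$transform$A), fallback = reg$rejected)
  }
  res <- if (cores > 1L) {
    parallel::mclapply(seq_len(Z), register_one, mc.cores = cores)
  } else {
    lapply(seq_len(Z), register_one)
  }
  res <- res[order(vapply(res, `[[`, integer(1), "z"))]
  fallbacks <- vapply(res, `[[`, logical(1), "fallback")
  if (any(fallbacks))
    warning("affine result rejected on slice(s) ",
            paste(which(fallbacks), collapse = ", "),
            "; translation-only fallback used")
  diagnostics <- data.frame(
    slice = seq_len(Z),
    mi_before = vapply(res, `[[`, numeric(1), "mi_before"),
    mi_after = vapply(res, `[[`, numeric(1), "mi_after"),
    det = vapply(res, `[[`, numeric(1), "det"),
    fallback = fallbacks)
  out <- list(aligned = with_slices(raw, lapply(res, `[[`, "aligned")),
              transforms = lapply(res, `[[`, "transform"),
              prealignment = pa,
              template = if (keep_template) tmpl,
              diagnostics = diagnostics, config = config,
              call = match.call())
  class(out) <- "amst"
  out
}

#' @rdname amst
#' @param ... passed on to [amst()].
#' @export
run_amst <- function(...) amst(...)

#' @rdname amst
#' @param x,object an `amst` fit.
#' @export
print.amst <- function(x, ...) {
  d <- stack_dim(x$aligned)
  cat(sprintf("<amst> %d slices of %d x %d aligned to a median-smoothed template\n",
              d["Z"], d["H"], d["W"]))
  cat(sprintf("  pre-alignment: %s;  median window: %d;  MI bins: %d\n",
              x$prealignment$method, x$config$median_window, x$config$bins))
  tmag <- sqrt(rowSums(coef(x)[, c("tx", "ty"), drop = FALSE]^2))
  cat(sprintf("  |t|: mean %.2f px, max %.2f px;  det(A) in [%.4f, %.4f]\n",
              mean(tmag), max(tmag), min(x$diagnostics$det),
              max(x$diagnostics$det)))
  if (any(x$diagnostics$fallback))
    cat("  translation-only fallback on slice(s):",
        paste(which(x$diagnostics$fallback), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname amst
#' @export
coef.amst <- function(object, ...) {
  t(vapply(object$transforms, affine_mu, numeric(6)))
}

#' @rdname amst
#' @export
summary.amst <- function(object, ...) {
  mu <- coef(object)
  tmag <- sqrt(rowSums(mu[, c("tx", "ty"), drop = FALSE]^2))
  structure(list(dim = stack_dim(object$aligned),
                 method = object$prealignment$method,
                 translation = summary(tmag),
                 det = summary(object$diagnostics$det),
                 mi_gain = summary(object$diagnostics$mi_after -
                                   object$diagnostics$mi_before),
                 fallbacks = which(object$diagnostics$fallback)),
            class = "summary.amst")
}

#' @export
print.summary.amst <- function(x, ...) {
  cat(sprintf("amst fit: %d slices (%d x %d), pre-alignment '%s'\n",
              x$dim["Z"], x$dim["H"], x$dim["W"], x$method))
  cat("\n|translation| (px):\n"); print(x$translation)
  cat("\ndet(A):\n"); print(x$det)
  cat("\nMI gain (bits):\n"); print(x$mi_gain)
  if (length(x$fallbacks))
    cat("\nfallback slices:", paste(x$fallbacks, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname amst
#' @param which diagnostics to plot: per-slice translation magnitude and
#'   transform determinant.
#' @export
plot.amst <- function(x, which = c("translation", "determinant"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  mu <- coef(x)
  old <- par(mfrow = c(length(which), 1), mar = c(4, 4, 1.5, 1))
  on.exit(par(old))
  if ("translation" %in% which) {
    tmag <- sqrt(rowSums(mu[, c("tx", "ty"), drop = FALSE]^2))
    plot(seq_len(nrow(mu)), tmag, type = "h", xlab = "slice",
         ylab = "|t| (px)", main = "per-slice translation")
  }
  if ("determinant" %in% which) {
    plot(seq_len(nrow(mu)), x$diagnostics$det, type = "l", xlab = "slice",
         ylab = "det(A)", main = "per-slice determinant")
    abline(h = 1, lty = 2)
  }
  invisible(x)
}

#' @rdname amst
#' @param region,z_range,... see [evaluate_alignment()].
#' @export
residuals.amst <- function(object, region = NULL, z_range = NULL, ...) {
  evaluate_alignment(object$aligned, region = region, z_range = z_range,
                     presmooth_sigma = object$config$presmooth_sigma)
}

#' Displacement-error trace of an alignment
#'
#' The alignment-quality metric: a feature-bearing region (512 x 512 px
#' by default, or the largest centred square that fits) is cropped from
#' the aligned stack; for each pair of adjacent slices inside the crop,
#' the residual translation that a local re-alignment would still apply
#' is estimated ([estimate_translation_pair()]) and its magnitude is
#' reported in nanometers (magnitude x pixel size). Local displacement
#' peaks flag individually distorted slices; a well-aligned stack has a
#' trace well below the pixel size.
#'
#' @param aligned an [image_stack()].
#' @param region `(x0, y0, w, h)` in 0-based pixels, or `NULL` for a
#'   centred square of side `min(512, H, W)`.
#' @param z_range 1-based inclusive `(z0, z1)` slice range, or `NULL`.
#' @param pixel_size_nm conversion factor; defaults to the stack metadata.
#' @param presmooth_sigma Gaussian sigma for the translation estimator.
#' @param region_label label stored with the trace.
#' @return A data frame of class `displacement_trace`: `transition`
#'   (1-based index of the later slice of each adjacent pair), `dx`,
#'   `dy` (px) and `error_nm`. Unalignable transitions are `NA`.
#' @export
evaluate_alignment <- function(aligned, region = NULL, z_range = NULL,
                               pixel_size_nm = NULL, presmooth_sigma = 1.6,
                               region_label = NULL) {
  stopifnot(inherits(aligned, "image_stack"))
  d <- stack_dim(aligned)
  if (is.null(pixel_size_nm)) pixel_size_nm <- aligned$pixel_size_xy_nm
  if (is.null(region)) {
    side <- min(512, d["H"], d["W"])
    region <- c((d["W"] - side) %/% 2, (d["H"] - side) %/% 2, side, side)
  }
  if (is.null(z_range)) z_range <- c(1L, d["Z"])
  crop <- crop_region(aligned, region[1], region[2], region[3], region[4],
                      z_range[1], z_range[2])
  Zc <- n_slices(crop)
  if (Zc < 2) stop("need at least 2 slices to evaluate")
  rows <- lapply(2:Zc, function(k) {
    o <- tryCatch(
      estimate_translation_pair(crop$slices[[k - 1]], crop$slices[[k]],
                                presmooth_sigma),
      error = function(e) NULL)
    if (is.null(o)) {
      data.frame(transition = z_range[1] + k - 1, dx = NA_real_,
                 dy = NA_real_, error_nm = NA_real_)
    } else {
      data.frame(transition = z_range[1] + k - 1, dx = o$dx, dy = o$dy,
                 error_nm = sqrt(o$dx^2 + o$dy^2) * pixel_size_nm)
    }
  })
  trace <- do.call(rbind, rows)
  attr(trace, "region") <- region
  attr(trace, "region_label") <- region_label
  attr(trace, "pixel_size_nm") <- pixel_size_nm
  class(trace) <- c("displacement_trace", "data.frame")
  trace
}

#' Summary statistics of a displacement trace
#'
#' @param trace a `displacement_trace` from [evaluate_alignment()] (or any
#'   data frame with an `error_nm` column).
#' @param threshold_nm threshold for the exceedance count (default 10 nm).
#' @return A list: `mean_nm`, `max_nm`, `n_above`, `threshold_nm`, `n`.
#' @export
trace_stats <- function(trace, threshold_nm = 10) {
  err <- trace$error_nm
  err <- err[is.finite(err)]
  if (length(err) == 0) stop("empty displacement trace")
  list(mean_nm = mean(err), max_nm = max(err),
       n_above = sum(err > threshold_nm), threshold_nm = threshold_nm,
       n = length(err))
}

#' @export
plot.displacement_trace <- function(x, ...) {
  plot(x$transition, x$error_nm, type = "l", xlab = "slice",
       ylab = "displacement error (nm)", ...)
  invisible(x)
}

#' Two-colour zy re-slice overlay of two alignments
#'
#' Re-slices both stacks in the zy-plane at a given x-column and overlays
#' them, alignment `a` in the red channel and `b` in cyan (green + blue),
#' so that differences between the two alignments appear as colour
#' fringes while agreement appears grayscale. Pure visualization.
#'
#' @param a,b [image_stack()]s of identical dimensions.
#' @param x_column 0-based column at which to re-slice.
#' @return An `H x Z x 3` RGB array (values in `[0, 1]`), suitable for
#'   `grid::grid.raster()` or [grDevices::as.raster()].
#' @export
overlay_reslice <- function(a, b, x_column) {
  stopifnot(inherits(a, "image_stack"), inherits(b, "image_stack"))
  if (!identical(stack_dim(a), stack_dim(b)))
    stop("stacks must have identical dimensions")
  d <- stack_dim(a)
  if (x_column < 0 || x_column >= d["W"]) stop("x_column out of range")
  ra <- vapply(a$slices, function(s) s[, x_column + 1], numeric(d["H"]))
  rb <- vapply(b$slices, function(s) s[, x_column + 1], numeric(d["H"]))
  lim <- range(ra, rb)
  norm <- function(m) if (diff(lim) > 0) (m - lim[1]) / diff(lim) else m * 0
  out <- array(0, unname(c(d["H"], d["Z"], 3)))
  out[, , 1] <- norm(ra)
  out[, , 2] <- norm(rb)
  out[, , 3] <- norm(rb)
  out
}
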