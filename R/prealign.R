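#' Sub-pixel translation offset
#'
#' A per-slice `(dx, dy)` translation in pixels. Applying an offset to a
#' slice moves its content by `+dx` columns and `+dy` rows, i.e.
#' `output(x) = input(x - dx)` (bilinear).
#'
#' @param dx,dy translation components in pixels (finite).
#' @param score optional match confidence (NCC peak or phase-correlation
#'   peak height).
#' @return An object of class `translation_offset`.
#' @export
translation_offset <- function(dx, dy, score = NA_real_) {
  dx <- unname(dx); dy <- unname(dy)
  if (!is.finite(dx) || !is.finite(dy))
    stop("translation offset must be finite")
  structure(list(dx = dx, dy = dy, score = score),
            class = "translation_offset")
}

#' @rdname translation_offset
#' @param x a `translation_offset`.
#' @param ... ignored.
#' @export
print.translation_offset <- function(x, ...) {
  cat(sprintf("<translation_offset> dx = %.4f, dy = %.4f px%s\n", x$dx, x$dy,
              if (is.finite(x$score)) sprintf(" (score %.3f)", x$score) else ""))
  invisible(x)
}

# 1-D quadratic refinement of a discrete peak from its two neighbours;
# returns the sub-sample offset in [-0.5, 0.5]
quad_refine <- function(cm, c0, cp) {
  den <- cm - 2 * c0 + cp
  if (!is.finite(den) || abs(den) < 1e-12) return(0)
  off <- 0.5 * (cm - cp) / den
  max(-0.5, min(0.5, off))
}

# Hann-windowed phase correlation. Returns the displacement d of `moving`
# relative to `fixed` (moving ~= fixed shifted by d) with sub-pixel
# quadratic refinement, and the correlation peak height.
phase_correlate <- function(fixed, moving) {
  H <- nrow(fixed); W <- ncol(fixed)
  wy <- if (H > 1) 0.5 - 0.5 * cos(2 * pi * (0:(H - 1)) / (H - 1)) else 1
  wx <- if (W > 1) 0.5 - 0.5 * cos(2 * pi * (0:(W - 1)) / (W - 1)) else 1
  wmat <- outer(wy, wx)
  F1 <- stats::fft((fixed - mean(fixed)) * wmat)
  F2 <- stats::fft((moving - mean(moving)) * wmat)
  # cross-power ordered so the peak lands at +d for moving = fixed
  # shifted by d
  R <- F2 * Conj(F1)
  mag <- Mod(R)
  R <- R / (mag + max(mag) * 1e-12 + 1e-300)
  r <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  peak <- which(r == max(r), arr.ind = TRUE)[1, ]
  i <- peak[1]; j <- peak[2]
  wrap <- function(idx, n) ((idx - 1) %% n) + 1
  sy <- quad_refine(r[wrap(i - 1, H), j], r[i, j], r[wrap(i + 1, H), j])
  sx <- quad_refine(r[i, wrap(j - 1, W)], r[i, j], r[i, wrap(j + 1, W)])
  dy <- (i - 1) + sy; if (dy > H / 2) dy <- dy - H
  dx <- (j - 1) + sx; if (dx > W / 2) dx <- dx - W
  list(dx = dx, dy = dy, peak = r[i, j])
}

#' Estimate the translation between two images
#'
#' Phase correlation with a Hann window after Gaussian presmoothing
#' (sigma = 1.6 px by default), refined to sub-pixel precision by a
#' quadratic fit around the correlation peak. The returned offset is the
#' displacement of `moving` relative to `fixed`: `moving` is approximately
#' `fixed` shifted by the offset, so applying the *negated* offset to
#' `moving` superimposes it onto `fixed`.
#'
#' @param fixed,moving numeric matrices of identical size.
#' @param presmooth_sigma Gaussian sigma in pixels applied to both images
#'   before correlation (default 1.6).
#' @param min_peak minimum acceptable phase-correlation peak height;
#'   below it the pair is declared unalignable.
#' @return A [translation_offset()] with the peak height as `score`.
#' @export
estimate_translation_pair <- function(fixed, moving, presmooth_sigma = 1.6,
                                      min_peak = 0.005) {
  if (!is.matrix(fixed) || !is.matrix(moving) ||
      !identical(dim(fixed), dim(moving)))
    stop("'fixed' and 'moving' must be matrices of identical dimensions")
  f <- gauss_blur_cpp(fixed, presmooth_sigma)
  m <- gauss_blur_cpp(moving, presmooth_sigma)
  if (stats::sd(f) == 0 || stats::sd(m) == 0)
    stop("unalignable pair: zero intensity variance after smoothing")
  pc <- phase_correlate(f, m)
  if (!is.finite(pc$peak) || pc$peak < min_peak)
    stop(sprintf("unalignable pair: no correlation peak (height %.4g)",
                 pc$peak))
  translation_offset(pc$dx, pc$dy, pc$peak)
}

#' Locate a template patch by normalized cross-correlation
#'
#' Exhaustively evaluates the normalized correlation coefficient of
#' `template` against `slice` for every integer placement within
#' `search_radius` of `search_center`, then refines the best placement to
#' sub-pixel precision with a separable quadratic fit to the 3x3
#' neighbourhood of the integer peak. Equal integer peaks are broken
#' towards the placement closest to `search_center` (then smallest y,
#' then smallest x). Positions refer to the template's top-left corner in
#' 0-based pixel coordinates.
#'
#' @param slice numeric matrix to search in.
#' @param template numeric matrix, strictly smaller than the search
#'   window, with nonzero intensity variance.
#' @param search_center numeric `(x, y)`: expected top-left placement.
#' @param search_radius search radius in pixels around `search_center`.
#' @return A [translation_offset()]: the displacement of the best
#'   placement from `search_center`, with the NCC value at the integer
#'   peak as `score` (in `[-1, 1]`).
#' @export
match_template <- function(slice, template, search_center, search_radius) {
  stopifnot(is.matrix(slice), is.matrix(template), search_radius >= 0)
  th <- nrow(template); tw <- ncol(template)
  H <- nrow(slice); W <- ncol(slice)
  if (th >= H || tw >= W)
    stop("template must be strictly smaller than the image")
  if (stats::sd(template) == 0)
    stop("degenerate template: zero intensity variance")
  cx <- search_center[1]; cy <- search_center[2]
  x0 <- max(0L, as.integer(floor(cx - search_radius)))
  x1 <- min(W - tw, as.integer(ceiling(cx + search_radius)))
  y0 <- max(0L, as.integer(floor(cy - search_radius)))
  y1 <- min(H - th, as.integer(ceiling(cy + search_radius)))
  if (x1 < x0 || y1 < y0) stop("search window is empty")
  sc <- ncc_search_cpp(slice, template, x0, x1, y0, y1)
  if (all(is.na(sc)))
    stop("degenerate template: search window has zero variance everywhere")
  best <- max(sc, na.rm = TRUE)
  cand <- which(sc >= best - 1e-12, arr.ind = TRUE)
  px <- x0 + cand[, 2] - 1
  py <- y0 + cand[, 1] - 1
  ord <- order((px - cx)^2 + (py - cy)^2, py, px)
  iy <- cand[ord[1], 1]; ix <- cand[ord[1], 2]
  sx <- sy <- 0
  if (ix > 1 && ix < ncol(sc) && !anyNA(sc[iy, (ix - 1):(ix + 1)]))
    sx <- quad_refine(sc[iy, ix - 1], sc[iy, ix], sc[iy, ix + 1])
  if (iy > 1 && iy < nrow(sc) && !anyNA(sc[(iy - 1):(iy + 1), ix]))
    sy <- quad_refine(sc[iy - 1, ix], sc[iy, ix], sc[iy + 1, ix])
  translation_offset(x0 + ix - 1 + sx - cx, y0 + iy - 1 + sy - cy,
                     score = best)
}

new_pre_alignment <- function(offsets, method, reference_slice = NULL,
                              scores = NULL, low_confidence = NULL) {
  colnames(offsets) <- c("dx", "dy")
  structure(list(offsets = offsets, method = method,
                 reference_slice = reference_slice, scores = scores,
                 low_confidence = low_confidence),
            class = "pre_alignment")
}

#' @rdname align_tm
#' @param x a `pre_alignment`.
#' @param ... ignored.
#' @export
print.pre_alignment <- function(x, ...) {
  cat(sprintf("<pre_alignment> method '%s', %d slices\n", x$method,
              nrow(x$offsets)))
  mags <- sqrt(rowSums(x$offsets^2))
  cat(sprintf("  |offset|: mean %.2f px, max %.2f px\n", mean(mags), max(mags)))
  if (!is.null(x$low_confidence) && any(x$low_confidence))
    cat("  low-confidence slices:",
        paste(which(x$low_confidence), collapse = ", "), "\n")
  invisible(x)
}

#' Translation-only pre-alignment by fiducial template matching
#'
#' Locates a fiducial template (typically a mark milled into the sample's
#' protective platinum coating, assumed to lie on a straight line along z)
#' in every slice by normalized cross-correlation and derives per-slice
#' translation offsets that put the fiducial at the same `(x, y)` in every
#' output slice. With `reference_slice = NULL` (the default) slices are
#' placed so the fiducial sits exactly at `template_position`, anchoring
#' the whole stack to an absolute frame; with a `reference_slice`, offsets
#' are relative to that slice (whose offset is `(0, 0)`).
#'
#' Slices whose NCC peak falls below `threshold` are flagged
#' low-confidence and their offsets replaced by linear interpolation from
#' the nearest confident neighbours (single aberrant slices are tolerated
#' downstream by the median template).
#'
#' @param stack an [image_stack()].
#' @param template fiducial patch (numeric matrix).
#' @param template_position `(x, y)` top-left position of the patch on the
#'   reference/anchor frame, 0-based pixels.
#' @param reference_slice optional 1-based slice index; `NULL` for
#'   absolute anchoring at `template_position`.
#' @param search_radius search radius in pixels (default: twice the
#'   template's larger side).
#' @param threshold NCC peak below which a match is low-confidence.
#' @return A `pre_alignment`: per-slice offsets (matrix with columns
#'   `dx`, `dy`), NCC scores, and low-confidence flags.
#' @export
align_tm <- function(stack, template, template_position,
                     reference_slice = NULL,
                     search_radius = 2 * max(dim(template)),
                     threshold = 0.5) {
  stopifnot(inherits(stack, "image_stack"))
  Z <- n_slices(stack)
  found <- matrix(NA_real_, Z, 2)
  scores <- numeric(Z)
  for (k in seq_len(Z)) {
    m <- tryCatch(
      match_template(stack$slices[[k]], template, template_position,
                     search_radius),
      error = function(e) stop("slice ", k, ": ", conditionMessage(e),
                               call. = FALSE))
    found[k, ] <- c(m$dx, m$dy)
    scores[k] <- m$score
  }
  low <- scores < threshold
  if (all(low))
    stop("template matching failed on every slice (all NCC peaks < ",
         threshold, ")")
  if (any(low)) {
    warning("low-confidence template match on slice(s) ",
            paste(which(low), collapse = ", "),
            "; offsets interpolated from neighbours")
    ok <- which(!low)
    for (j in 1:2)
      found[low, j] <- stats::approx(ok, found[ok, j], xout = which(low),
                                     rule = 2)$y
  }
  offsets <- if (is.null(reference_slice)) {
    -found
  } else {
    stopifnot(reference_slice >= 1, reference_slice <= Z)
    matrix(rep(found[reference_slice, ], each = Z), Z, 2) - found
  }
  new_pre_alignment(offsets, "tm", reference_slice, scores, low)
}

#' Translation-only pre-alignment by slice-to-slice feature correlation
#'
#' Estimates the translation between each slice and its predecessor
#' ([estimate_translation_pair()], Gaussian presmoothing sigma = 1.6 px)
#' and accumulates the pairwise displacements into absolute offsets with
#' slice 1 fixed at `(0, 0)`. Preserves local structure but, like any
#' slice-to-slice scheme, reproduces rather than corrects long-range
#' drift.
#'
#' @param stack an [image_stack()] with at least 2 slices.
#' @param presmooth_sigma Gaussian sigma in pixels (default 1.6).
#' @return A `pre_alignment` with `method = "feature"`.
#' @export
align_feature <- function(stack, presmooth_sigma = 1.6) {
  stopifnot(inherits(stack, "image_stack"))
  Z <- n_slices(stack)
  if (Z < 2) stop("feature pre-alignment needs at least 2 slices")
  d <- matrix(0, Z, 2)
  scores <- rep(NA_real_, Z)
  for (k in 2:Z) {
    o <- tryCatch(
      estimate_translation_pair(stack$slices[[k - 1]], stack$slices[[k]],
                                presmooth_sigma),
      error = function(e) stop("slices ", k - 1, " -> ", k, ": ",
                               conditionMessage(e), call. = FALSE))
    d[k, ] <- c(o$dx, o$dy)
    scores[k] <- o$score
  }
  cum <- apply(d, 2, cumsum)
  new_pre_alignment(-cum, "feature", NULL, scores, NULL)
}

#' Apply a pre-alignment to a stack
#'
#' Resamples each slice by its offset with bilinear interpolation onto the
#' original canvas (fixed canvas, no growth); pixels falling outside the
#' source are set to `fill`. Integer offsets degenerate to an exact copy
#' on the overlapping region.
#'
#' @param stack an [image_stack()].
#' @param pa a `pre_alignment` from [align_tm()] or [align_feature()].
#' @param fill background fill value (default 0).
#' @return An [image_stack()] with the same dimensions and metadata.
#' @export
apply_prealignment <- function(stack, pa, fill = 0) {
  stopifnot(inherits(stack, "image_stack"), inherits(pa, "pre_alignment"))
  Z <- n_slices(stack)
  if (nrow(pa$offsets) != Z)
    stop("pre-alignment has ", nrow(pa$offsets), " offsets for ", Z, " slices")
  slices <- lapply(seq_len(Z), function(k)
    warp_affine_cpp(stack$slices[[k]],
                    c(1, 0, 0, 1, -pa$offsets[k, 1], -pa$offsets[k, 2]),
                    0, 0, fill))
  with_slices(stack, slices)
}

#' Read/write pre-alignment offsets
#'
#' Offsets are stored as a plain-text table `(slice, dx, dy, score)` —
#' CSV, or JSON when `path` ends in `.json`.
#'
#' @param pa a `pre_alignment`.
#' @param path output file.
#' @return `write_offsets` returns `path` invisibly; `read_offsets`
#'   returns a `pre_alignment`.
#' @export
write_offsets <- function(pa, path) {
  stopifnot(inherits(pa, "pre_alignment"))
  df <- data.frame(slice = seq_len(nrow(pa$offsets)),
                   dx = pa$offsets[, 1], dy = pa$offsets[, 2],
                   score = if (is.null(pa$scores)) NA_real_ else pa$scores)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(method = pa$method,
                              reference_slice = pa$reference_slice,
                              offsets = df),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_offsets
#' @param method pre-alignment method label for CSV files (JSON files
#'   store it themselves).
#' @export
read_offsets <- function(path, method = "tm") {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- rec$offsets
    method <- rec$method
    ref <- rec$reference_slice
  } else {
    df <- utils::read.csv(path)
    ref <- NULL
  }
  new_pre_alignment(cbind(df$dx, df$dy), method, ref, df$score)
}
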