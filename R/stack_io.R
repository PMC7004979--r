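#' Construct an image stack
#'
#' An `image_stack` is an ordered z-stack of equally sized 2-D grayscale
#' slices with physical pixel metadata. Slices are stored as numeric
#' matrices (rows = y, columns = x); the nominal storage type is kept in
#' `dtype` so that integer data survive a save/load round trip bit-exactly.
#'
#' @param slices list of numeric matrices, all with identical dimensions.
#' @param pixel_size_xy_nm lateral pixel size in nanometers (> 0).
#' @param slice_thickness_nm slice spacing in nanometers (> 0).
#' @param dtype storage type: `"uint8"`, `"uint16"` or `"float32"`.
#' @param names optional character vector of per-slice identifiers.
#' @return An object of class `image_stack`.
#' @examples
#' s <- image_stack(replicate(4, matrix(0:255, 16, 16), simplify = FALSE))
#' n_slices(s)
#' @export
image_stack <- function(slices, pixel_size_xy_nm = 5, slice_thickness_nm = 8,
                        dtype = c("uint8", "uint16", "float32"), names = NULL) {
  dtype <- match.arg(dtype)
  if (!is.list(slices) || length(slices) == 0L)
    stop("'slices' must be a non-empty list of matrices")
  dims <- dim(slices[[1]])
  for (k in seq_along(slices)) {
    if (!is.matrix(slices[[k]]) || !is.numeric(slices[[k]]))
      stop("slice ", k, " is not a numeric matrix")
    if (!identical(dim(slices[[k]]), dims))
      stop("slice ", k, if (!is.null(names)) paste0(" ('", names[k], "')"),
           " has dimensions ", paste(dim(slices[[k]]), collapse = "x"),
           ", expected ", paste(dims, collapse = "x"))
    storage.mode(slices[[k]]) <- "double"
  }
  stopifnot(pixel_size_xy_nm > 0, slice_thickness_nm > 0)
  if (!is.null(names) && length(names) != length(slices))
    stop("'names' length must match the number of slices")
  structure(list(slices = slices,
                 pixel_size_xy_nm = pixel_size_xy_nm,
                 slice_thickness_nm = slice_thickness_nm,
                 dtype = dtype, names = names),
            class = "image_stack")
}

#' @rdname image_stack
#' @param x,stack an `image_stack`.
#' @export
n_slices <- function(stack) length(stack$slices)

#' @rdname image_stack
#' @export
stack_dim <- function(stack) {
  d <- dim(stack$slices[[1]])
  c(Z = length(stack$slices), H = d[1], W = d[2])
}

#' @rdname image_stack
#' @param ... ignored.
#' @export
print.image_stack <- function(x, ...) {
  d <- stack_dim(x)
  cat(sprintf("<image_stack> %d slices of %d x %d (H x W), dtype %s\n",
              d["Z"], d["H"], d["W"], x$dtype))
  cat(sprintf("  pixel size %.3g nm (xy), slice thickness %.3g nm (z)\n",
              x$pixel_size_xy_nm, x$slice_thickness_nm))
  invisible(x)
}

#' @rdname image_stack
#' @export
as.array.image_stack <- function(x, ...) {
  d <- unname(stack_dim(x))
  array(unlist(x$slices, use.names = FALSE), dim = d[c(2, 3, 1)])
}

dtype_max <- function(dtype)
  switch(dtype, uint8 = 255, uint16 = 65535, float32 = 1)

#' Natural-order sort of file names
#'
#' Sorts so that embedded integers compare numerically (`slice_2` before
#' `slice_10`), matching microscope exports that do not zero-pad.
#' @param x character vector.
#' @return `x` reordered.
#' @export
natural_sort <- function(x) {
  if (length(x) < 2) return(x)
  pieces <- regmatches(x, gregexpr("[0-9]+|[^0-9]+", x))
  maxlen <- max(lengths(pieces))
  keys <- lapply(seq_len(maxlen), function(i) {
    part <- vapply(pieces, function(p) if (i <= length(p)) p[i] else "",
                   character(1))
    num <- suppressWarnings(as.numeric(part))
    if (all(!is.na(num) | part == "")) {
      num[part == ""] <- -Inf
      num
    } else part
  })
  x[do.call(order, keys)]
}

tiff_extensions <- c("tif", "tiff", "TIF", "TIFF")

# Convert one page read with info=TRUE (values in [0,1]) to stored units.
tiff_page_to_slice <- function(img, what) {
  bps <- attr(img, "bits.per.sample")
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1]
    else stop(what, " is not a single-channel grayscale image")
  }
  if (is.null(bps)) bps <- 8L
  dtype <- switch(as.character(bps), "8" = "uint8", "16" = "uint16",
                  "32" = "float32",
                  stop(what, ": unsupported bit depth ", bps))
  vals <- if (dtype == "float32") img else round(img * dtype_max(dtype))
  attributes(vals) <- list(dim = dim(img))
  list(img = vals, dtype = dtype)
}

read_gray_tiff <- function(path) {
  img <- tiff::readTIFF(path, info = TRUE, all = FALSE)
  tiff_page_to_slice(img, paste0("'", path, "'"))
}

#' Load an image stack from disk
#'
#' @param path directory of single-page TIFFs (`kind = "tiff_dir"`) or a
#'   multi-page TIFF file (`kind = "tiff_multipage"`).
#' @param kind on-disk layout.
#' @param pixel_size_xy_nm,slice_thickness_nm physical metadata to attach.
#' @return An [image_stack()]. Directory loads are ordered by natural sort
#'   of the file names; multi-page loads follow page order.
#' @seealso [save_stack()]
#' @export
load_stack <- function(path, kind = c("tiff_dir", "tiff_multipage"),
                       pixel_size_xy_nm = 5, slice_thickness_nm = 8) {
  kind <- match.arg(kind)
  if (kind == "tiff_dir") {
    if (!dir.exists(path)) stop("directory '", path, "' does not exist")
    files <- list.files(path, full.names = FALSE)
    files <- files[tools::file_ext(files) %in% tiff_extensions]
    if (length(files) == 0L) stop("no TIFF files found in '", path, "'")
    files <- natural_sort(files)
    slices <- vector("list", length(files))
    dims <- NULL
    dtype <- NULL
    for (k in seq_along(files)) {
      pg <- read_gray_tiff(file.path(path, files[k]))
      if (is.null(dims)) {
        dims <- dim(pg$img)
        dtype <- pg$dtype
      } else if (!identical(dim(pg$img), dims)) {
        stop("slice '", files[k], "' has dimensions ",
             paste(dim(pg$img), collapse = "x"), ", expected ",
             paste(dims, collapse = "x"))
      } else if (!identical(pg$dtype, dtype)) {
        stop("slice '", files[k], "' has dtype ", pg$dtype,
             ", expected ", dtype)
      }
      slices[[k]] <- pg$img
    }
    image_stack(slices, pixel_size_xy_nm, slice_thickness_nm, dtype,
                names = files)
  } else {
    if (!file.exists(path)) stop("file '", path, "' does not exist")
    pages <- tiff::readTIFF(path, info = TRUE, all = TRUE)
    if (length(pages) == 0L) stop("'", path, "' contains no pages")
    parsed <- lapply(seq_along(pages), function(k)
      tiff_page_to_slice(pages[[k]], paste0("page ", k, " of '", path, "'")))
    image_stack(lapply(parsed, `[[`, "img"), pixel_size_xy_nm,
                slice_thickness_nm, parsed[[1]]$dtype)
  }
}

#' Save an image stack to disk
#'
#' Integer stacks (`uint8`, `uint16`) round-trip bit-exactly. Float stacks
#' are written as 32-bit float TIFF and must contain values in `[0, 1]`;
#' saving float data at 8/16-bit depth requires rescaling first (no silent
#' quantization is performed).
#'
#' @param stack an [image_stack()].
#' @param path output directory (`tiff_dir`) or file (`tiff_multipage`).
#' @param kind on-disk layout, as in [load_stack()].
#' @return Invisibly, `path`.
#' @export
save_stack <- function(stack, path, kind = c("tiff_dir", "tiff_multipage")) {
  kind <- match.arg(kind)
  stopifnot(inherits(stack, "image_stack"))
  if (stack$dtype == "float32") {
    rng <- range(vapply(stack$slices, range, numeric(2)))
    if (rng[1] < 0 || rng[2] > 1)
      stop("float32 stacks must be rescaled to [0, 1] before saving; ",
           "refusing to quantize silently (range ",
           sprintf("[%.3g, %.3g])", rng[1], rng[2]))
    bits <- 32L
    scale <- 1
  } else {
    bits <- if (stack$dtype == "uint8") 8L else 16L
    scale <- dtype_max(stack$dtype)
  }
  if (kind == "tiff_dir") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    nm <- stack$names
    if (is.null(nm)) nm <- sprintf("slice_%04d.tif", seq_along(stack$slices))
    for (k in seq_along(stack$slices)) {
      ok <- tiff::writeTIFF(stack$slices[[k]] / scale, file.path(path, nm[k]),
                            bits.per.sample = bits, reduce = FALSE)
      if (!isTRUE(ok == 1L)) stop("failed to write '", nm[k], "'")
    }
  } else {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    tiff::writeTIFF(lapply(stack$slices, function(s) s / scale), path,
                    bits.per.sample = bits, reduce = FALSE)
  }
  invisible(path)
}

#' Crop a sub-volume from a stack
#'
#' @param stack an [image_stack()].
#' @param x0,y0 0-based pixel coordinates of the crop's top-left corner.
#' @param w,h crop width and height in pixels.
#' @param z0,z1 1-based inclusive slice range (defaults: whole stack).
#' @return An [image_stack()] of dimensions `(z1 - z0 + 1, h, w)` with the
#'   pixel metadata preserved.
#' @export
crop_region <- function(stack, x0, y0, w, h, z0 = 1L, z1 = n_slices(stack)) {
  stopifnot(inherits(stack, "image_stack"))
  d <- stack_dim(stack)
  if (x0 < 0 || y0 < 0 || w < 1 || h < 1 || x0 + w > d["W"] || y0 + h > d["H"])
    stop(sprintf("crop rectangle (x0=%d, y0=%d, w=%d, h=%d) exceeds the %d x %d canvas",
                 x0, y0, w, h, d["H"], d["W"]))
  if (z0 < 1 || z1 > d["Z"] || z0 > z1)
    stop("invalid slice range [", z0, ", ", z1, "] for a stack of ",
         d["Z"], " slices")
  slices <- lapply(stack$slices[z0:z1], function(s)
    s[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), drop = FALSE])
  image_stack(slices, stack$pixel_size_xy_nm, stack$slice_thickness_nm,
              stack$dtype,
              names = if (!is.null(stack$names)) stack$names[z0:z1])
}

# float32 view of one slice for registration math (raw integers are kept
# for output; all metric/warp computation runs on double copies anyway)
slice_of <- function(stack, z) stack$slices[[z]]

# replace slices, preserving metadata; used by alignment stages
with_slices <- function(stack, slices, dtype = stack$dtype) {
  out <- stack
  out$slices <- slices
  out$dtype <- dtype
  out
}
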