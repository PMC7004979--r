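#' Median-smoothed template stack
#'
#' Filters the pre-aligned stack with a median filter along the z-axis
#' only (default window: 15 slices; no filtering along x or y), yielding
#' the template dataset to which the raw data is subsequently registered.
#' Because any set of fewer than half-a-window consecutive aberrant slices
#' cannot move a median, slices distorted by auto-focus/auto-stigmation
#' events are overwritten by their neighbours' consensus while in-plane
#' morphology is untouched.
#'
#' At the stack ends the window shrinks (it is clipped to the available
#' slices) rather than reflecting, so potentially distorted end slices are
#' not double-weighted; for the resulting even-sized windows the *lower*
#' median is taken, preserving an actually observed intensity value (and
#' integer dtypes). Background pixels introduced by the pre-alignment
#' participate in the median at their fill value.
#'
#' @param prealigned an [image_stack()] (typically the output of
#'   [apply_prealignment()]).
#' @param window odd z-window size, >= 3 (default 15).
#' @return An [image_stack()] of class `c("template_stack",
#'   "image_stack")` with the source dimensions and metadata; the window
#'   size is recorded in attribute `median_window`.
#' @examples
#' s <- image_stack(replicate(20, matrix(7, 8, 8), simplify = FALSE))
#' t <- compute_template(s, 5)  # constant stack is a fixed point
#' @export
compute_template <- function(prealigned, window = 15L) {
  stopifnot(inherits(prealigned, "image_stack"))
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("'window' must be odd")
  if (window < 3L) stop("'window' must be >= 3")
  d <- stack_dim(prealigned)
  vol <- as.array.image_stack(prealigned)
  med <- zmedian_cpp(as.numeric(vol), d["H"], d["W"], d["Z"], window)
  dim(med) <- dim(vol)
  slices <- lapply(seq_len(d["Z"]), function(z) med[, , z])
  out <- with_slices(prealigned, slices)
  class(out) <- c("template_stack", "image_stack")
  attr(out, "median_window") <- window
  out
}
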