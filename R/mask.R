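#' Binary masks
#'
#' Throughout the package a binary mask is a plain logical matrix in
#' row-major (row, col) orientation: entry `[i, j]` is pixel
#' (row = i - 1, col = j - 1) in the 0-based coordinate convention used by
#' all polygon and file interfaces, with row 0 at the top of the image.
#' `as_binary_mask()` validates and normalises an object into this form.
#'
#' @param x a logical (or coercible numeric 0/1) matrix with at least one
#'   row and one column.
#' @return a logical matrix.
#' @examples
#' m <- as_binary_mask(matrix(c(1, 0, 0, 1), 2, 2))
#' mask_area(m)
#' @export
as_binary_mask <- function(x) {
  if (!is.matrix(x)) stop_cm("a binary mask must be a matrix")
  if (nrow(x) < 1 || ncol(x) < 1) stop_cm("a binary mask needs height >= 1 and width >= 1")
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop_cm("numeric mask values must be 0 or 1")
    x <- x == 1
  }
  if (!is.logical(x)) stop_cm("a binary mask must be logical or numeric 0/1")
  if (anyNA(x)) stop_cm("a binary mask may not contain NA")
  x
}

#' Number of true pixels in a mask
#' @param mask a binary mask (logical matrix).
#' @return integer pixel count.
#' @export
mask_area <- function(mask) {
  sum(as_binary_mask(mask))
}

#' Test pixelwise containment of one mask in another
#'
#' @param inner,outer binary masks of identical shape.
#' @return `TRUE` when every true pixel of `inner` is true in `outer`.
#' @export
mask_subset <- function(inner, outer) {
  inner <- as_binary_mask(inner)
  outer <- as_binary_mask(outer)
  check_same_shape(inner, outer)
  !any(inner & !outer)
}

check_same_shape <- function(a, b) {
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b)) {
    stop_cm(sprintf(
      "mask shapes differ: %dx%d vs %dx%d",
      nrow(a), ncol(a), nrow(b), ncol(b)
    ))
  }
  invisible(TRUE)
}

#' Query a mask at 0-based (row, col) positions
#'
#' Out-of-bounds queries are an error, never silently `FALSE`.
#'
#' @param mask a binary mask.
#' @param row,col 0-based pixel coordinates (vectors of equal length).
#' @return logical vector of pixel values.
#' @export
mask_at <- function(mask, row, col) {
  mask <- as_binary_mask(mask)
  if (any(row < 0 | row >= nrow(mask) | col < 0 | col >= ncol(mask))) {
    stop_cm("mask query outside [0, height) x [0, width)")
  }
  mask[cbind(row + 1L, col + 1L)]
}
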