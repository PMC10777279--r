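#' Dice overlap coefficient
#'
#' Spatial-overlap statistic `2|A∩B| / (|A| + |B|)`, ranging from 0 for no
#' overlap to 1 for perfect agreement. Two empty masks agree on absence and
#' score 1; an empty mask against a non-empty one scores 0.
#'
#' @param a,b binary masks of identical shape.
#' @return number in `[0, 1]`.
#' @examples
#' m <- matrix(FALSE, 4, 4)
#' a <- m; a[1:2, 1] <- TRUE
#' b <- m; b[2:3, 1] <- TRUE
#' dice(a, b) # 2 * 1 / (2 + 2) = 0.5
#' @export
dice <- function(a, b) {
  a <- as_binary_mask(a)
  b <- as_binary_mask(b)
  check_same_shape(a, b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Fraction of skin area marked, in percent
#'
#' @param mask a binary mask, clipped to `skin`.
#' @param skin the skin mask (non-empty).
#' @return percentage in `[0, 100]`.
#' @export
surface_area_fraction <- function(mask, skin) {
  mask <- as_binary_mask(mask)
  skin <- as_binary_mask(skin)
  check_same_shape(mask, skin)
  if (mask_area(skin) == 0) stop_cm("skin mask is empty")
  if (!mask_subset(mask, skin)) {
    stop_cm("mask has pixels outside the skin mask (clipping contract violated)")
  }
  100 * mask_area(mask) / mask_area(skin)
}

#' Surface area error, in percentage points of skin area
#'
#' Absolute difference between the percentage of skin area marked in the
#' prediction and in the ground truth. A pure area metric: it ignores where
#' pixels are marked, which is why it is paired with Dice. If the ground
#' truth covers 10% of the skin and the prediction 25%, the error is 15.
#'
#' @param pred,gt binary masks, both clipped to `skin`.
#' @param skin the skin mask.
#' @return percentage points in `[0, 100]`.
#' @export
surface_area_error <- function(pred, gt, skin) {
  abs(surface_area_fraction(pred, skin) - surface_area_fraction(gt, skin))
}

#' Score a predicted mask against an image's ground truth
#'
#' @param pred predicted binary mask, clipped to the image's skin mask.
#' @param image a [skin_image()].
#' @param label identifier for the prediction (crowd name or rater id).
#' @return one-row data frame with columns image_id, label, dice,
#'   surface_area_error, gt_fraction, pred_fraction.
#' @export
score_image <- function(pred, image, label = "pred") {
  gt_fraction <- surface_area_fraction(image$gt_affected, image$skin_mask)
  pred_fraction <- surface_area_fraction(pred, image$skin_mask)
  data.frame(
    image_id = image$image_id, label = as.character(label),
    dice = dice(pred, image$gt_affected),
    surface_area_error = abs(gt_fraction - pred_fraction),
    gt_fraction = gt_fraction, pred_fraction = pred_fraction,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
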