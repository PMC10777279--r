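#' One 2D view of a photographed skin area
#'
#' Bundles the skin mask (pixels that depict skin), the expert ground-truth
#' mask of affected skin, and the identifiers tying the view to its parent
#' stereoscopic photo and to the study split. The ground-truth mask must be
#' contained in the skin mask and the skin mask must be non-empty.
#'
#' @param image_id unique image identifier.
#' @param photo_id identifier of the parent 3D photo this view projects.
#' @param view_label viewing-angle label; `"0_0"` denotes the original view.
#' @param skin_mask,gt_affected binary masks of identical shape.
#' @param split `"gt_provided"` (expert answer may be shown as feedback) or
#'   `"gt_withheld"` (evaluation set, answer never released).
#' @return an object of class `skin_image`.
#' @export
skin_image <- function(image_id, photo_id, view_label, skin_mask, gt_affected,
                       split = c("gt_withheld", "gt_provided")) {
  split <- match.arg(split)
  skin_mask <- as_binary_mask(skin_mask)
  gt_affected <- as_binary_mask(gt_affected)
  check_same_shape(skin_mask, gt_affected)
  if (mask_area(skin_mask) < 1) stop_cm("skin mask must contain at least one pixel")
  if (!mask_subset(gt_affected, skin_mask)) {
    stop_cm("ground-truth affected mask must be contained in the skin mask")
  }
  structure(
    list(
      image_id = as.character(image_id), photo_id = as.character(photo_id),
      view_label = as.character(view_label), skin_mask = skin_mask,
      gt_affected = gt_affected, split = split
    ),
    class = "skin_image"
  )
}

#' @export
print.skin_image <- function(x, ...) {
  cat(sprintf(
    "<skin_image %s> photo %s view %s (%s), %dx%d, skin %d px, affected %.1f%% of skin\n",
    x$image_id, x$photo_id, x$view_label, x$split,
    nrow(x$skin_mask), ncol(x$skin_mask), mask_area(x$skin_mask),
    100 * mask_area(x$gt_affected) / mask_area(x$skin_mask)
  ))
  invisible(x)
}

#' A simulated rater and their skill parameters
#'
#' The skill model is the package's stand-in for real human variability:
#' boundary jitter (positional noise on polygon nodes, px), per-region
#' detection probability, an expected count of spurious marked regions per
#' image, and the number of polygon nodes the rater budgets per outline.
#'
#' @param rater_id unique rater identifier.
#' @param arm feedback arm, `"high_feedback"` or `"low_feedback"`.
#' @param enrollment_order positive integer, unique within a study.
#' @param boundary_jitter_sigma node jitter SD in pixels (>= 0).
#' @param region_detection_prob probability in `[0, 1]` that a ground-truth
#'   region is noticed and outlined.
#' @param false_positive_rate expected number of spurious regions per image.
#' @param node_budget maximum nodes per polygon outline (>= 3).
#' @return an object of class `rater_profile`.
#' @export
rater_profile <- function(rater_id, arm = c("low_feedback", "high_feedback"),
                          enrollment_order,
                          boundary_jitter_sigma = 2,
                          region_detection_prob = 0.9,
                          false_positive_rate = 0.1,
                          node_budget = 24L) {
  arm <- match.arg(arm)
  enrollment_order <- as.integer(enrollment_order)
  if (is.na(enrollment_order) || enrollment_order < 1) {
    stop_cm("enrollment_order must be a positive integer")
  }
  if (boundary_jitter_sigma < 0) stop_cm("boundary_jitter_sigma must be >= 0")
  if (region_detection_prob < 0 || region_detection_prob > 1) {
    stop_cm("region_detection_prob must be in [0, 1]")
  }
  if (false_positive_rate < 0) stop_cm("false_positive_rate must be >= 0")
  node_budget <- as.integer(node_budget)
  if (node_budget < 3L) stop_cm("node_budget must be >= 3")
  structure(
    list(
      rater_id = as.character(rater_id), arm = arm,
      enrollment_order = enrollment_order,
      skill = list(
        boundary_jitter_sigma = boundary_jitter_sigma,
        region_detection_prob = region_detection_prob,
        false_positive_rate = false_positive_rate,
        node_budget = node_budget
      )
    ),
    class = "rater_profile"
  )
}

#' One rater's demarcation of one image
#'
#' Holds the submitted polygon node loops (0-based continuous (row, col)
#' coordinates), their rasterization clipped to the image's skin mask, and
#' the order of submission among that image's demarcations. An empty polygon
#' list (nothing marked) is a valid submission with an all-false mask.
#'
#' @param rater_id,image_id identifiers.
#' @param polygons list of closed vertex loops, each an `n x 2` numeric
#'   matrix of (row, col) coordinates; may be empty.
#' @param mask rasterized binary mask; must be contained in `skin_mask`.
#' @param sequence_index 1-based order of submission for the image.
#' @param skin_mask the image's skin mask, used only to validate clipping.
#' @param rater_seq optional 1-based position of this submission in the
#'   rater's own chronological stream (used by learning curves).
#' @return an object of class `demarcation`.
#' @export
demarcation <- function(rater_id, image_id, polygons, mask, sequence_index,
                        skin_mask = NULL, rater_seq = NA_integer_) {
  mask <- as_binary_mask(mask)
  if (!is.list(polygons)) stop_cm("polygons must be a list of loops")
  for (p in polygons) {
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3) {
      stop_cm("each polygon loop must be an n x 2 matrix with n >= 3")
    }
  }
  if (length(polygons) == 0 && mask_area(mask) > 0) {
    stop_cm("a demarcation without polygons must have an all-false mask")
  }
  if (!is.null(skin_mask) && !mask_subset(mask, skin_mask)) {
    stop_cm("demarcation mask must be clipped to the image's skin mask")
  }
  sequence_index <- as.integer(sequence_index)
  if (is.na(sequence_index) || sequence_index < 1) {
    stop_cm("sequence_index must be a positive integer")
  }
  structure(
    list(
      rater_id = as.character(rater_id), image_id = as.character(image_id),
      polygons = polygons, mask = mask, sequence_index = sequence_index,
      rater_seq = as.integer(rater_seq)
    ),
    class = "demarcation"
  )
}

#' A full demarcation study
#'
#' Container for the images, rater profiles, demarcations, feedback-exposure
#' log, and the generating configuration. Constructor-checked invariants:
#' every demarcation references an existing rater and image, its mask is
#' clipped to that image's skin mask, at most one demarcation exists per
#' (rater, image) pair, and per image the sequence indices form 1..n.
#'
#' @param images list of [skin_image()] objects.
#' @param raters list of [rater_profile()] objects.
#' @param demarcations list of [demarcation()] objects.
#' @param exposure data frame logging feedback exposure
#'   (rater_id, image_id, rater_seq), or `NULL`.
#' @param config_echo the generating configuration (list), or `NULL`.
#' @return an object of class `study_dataset`.
#' @export
study_dataset <- function(images, raters, demarcations,
                          exposure = NULL, config_echo = NULL) {
  names(images) <- vapply(images, function(x) x$image_id, character(1))
  names(raters) <- vapply(raters, function(x) x$rater_id, character(1))
  if (anyDuplicated(names(images))) stop_cm("duplicate image_id")
  if (anyDuplicated(names(raters))) stop_cm("duplicate rater_id")
  enr <- vapply(raters, function(x) x$enrollment_order, integer(1))
  if (anyDuplicated(enr)) stop_cm("enrollment_order must be unique within a study")

  key <- vapply(demarcations, function(d) paste(d$rater_id, d$image_id, sep = "\r"), character(1))
  if (anyDuplicated(key)) stop_cm("at most one demarcation per (rater, image) pair")
  for (d in demarcations) {
    if (!d$rater_id %in% names(raters)) stop_cm("demarcation references unknown rater ", d$rater_id)
    if (!d$image_id %in% names(images)) stop_cm("demarcation references unknown image ", d$image_id)
    if (!mask_subset(d$mask, images[[d$image_id]]$skin_mask)) {
      stop_cm("demarcation mask exceeds skin mask for image ", d$image_id)
    }
  }
  img_ids <- vapply(demarcations, function(d) d$image_id, character(1))
  for (id in unique(img_ids)) {
    sq <- sort(vapply(demarcations[img_ids == id], function(d) d$sequence_index, integer(1)))
    if (!identical(sq, seq_along(sq))) {
      stop_cm("sequence_index values for image ", id, " must form 1..n with no gaps")
    }
  }
  structure(
    list(
      images = images, raters = raters, demarcations = demarcations,
      exposure = exposure, config_echo = config_echo
    ),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "<study_dataset> %d images (%d photos), %d raters, %d demarcations\n",
    length(x$images),
    length(unique(vapply(x$images, function(i) i$photo_id, character(1)))),
    length(x$raters), length(x$demarcations)
  ))
  invisible(x)
}

#' Tabular views of a study dataset
#'
#' @param dataset a [study_dataset()].
#' @return `images_table()`: one row per image (image_id, photo_id,
#'   view_label, split, height, width, affected flag); `raters_table()`: one
#'   row per rater with skill columns; `demarcations_table()`: one row per
#'   demarcation (no masks or polygons).
#' @export
images_table <- function(dataset) {
  do.call(rbind, lapply(dataset$images, function(im) {
    data.frame(
      image_id = im$image_id, photo_id = im$photo_id,
      view_label = im$view_label, split = im$split,
      height = nrow(im$skin_mask), width = ncol(im$skin_mask),
      affected = mask_area(im$gt_affected) > 0,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
}

#' @rdname images_table
#' @export
raters_table <- function(dataset) {
  do.call(rbind, lapply(dataset$raters, function(r) {
    data.frame(
      rater_id = r$rater_id, arm = r$arm,
      enrollment_order = r$enrollment_order,
      boundary_jitter_sigma = r$skill$boundary_jitter_sigma,
      region_detection_prob = r$skill$region_detection_prob,
      false_positive_rate = r$skill$false_positive_rate,
      node_budget = r$skill$node_budget,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
}

#' @rdname images_table
#' @export
demarcations_table <- function(dataset) {
  do.call(rbind, lapply(dataset$demarcations, function(d) {
    data.frame(
      rater_id = d$rater_id, image_id = d$image_id,
      sequence_index = d$sequence_index, rater_seq = d$rater_seq,
      marked_area = mask_area(d$mask),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
}

#' Demarcations of one image
#'
#' @param dataset a [study_dataset()].
#' @param image_id image identifier.
#' @param arm optionally restrict to one feedback arm.
#' @return list of [demarcation()] objects ordered by `sequence_index`.
#' @export
image_demarcations <- function(dataset, image_id, arm = NULL) {
  ds <- Filter(function(d) d$image_id == image_id, dataset$demarcations)
  if (!is.null(arm)) {
    ds <- Filter(function(d) dataset$raters[[d$rater_id]]$arm == arm, ds)
  }
  ds[order(vapply(ds, function(d) d$sequence_index, integer(1)))]
}
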