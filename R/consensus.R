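#' Per-pixel vote counts for one image
#'
#' Labels each pixel with the number of raters in the list who marked it as
#' affected. All demarcations must belong to the same image and share one
#' mask shape.
#'
#' @param demarcations non-empty list of [demarcation()]s for one image.
#' @return list of class `vote_count_map` with fields `image_id`,
#'   `n_raters`, and `counts` (integer matrix).
#' @export
vote_counts <- function(demarcations) {
  if (length(demarcations) == 0) stop_cm("vote_counts needs at least one demarcation")
  ids <- unique(vapply(demarcations, function(d) d$image_id, character(1)))
  if (length(ids) != 1) stop_cm("demarcations mix image_ids: ", paste(ids, collapse = ", "))
  ref <- demarcations[[1]]$mask
  counts <- matrix(0L, nrow(ref), ncol(ref))
  for (d in demarcations) {
    check_same_shape(ref, d$mask)
    counts <- counts + d$mask
  }
  structure(
    list(image_id = ids, n_raters = length(demarcations), counts = counts),
    class = "vote_count_map"
  )
}

#' Plurality-vote consensus mask
#'
#' The consensus demarcation consists of all pixels marked by at least
#' `threshold` (default 50%) of the crowd's raters; pixels at exactly the
#' threshold — e.g. 2 votes out of 4 — are included, reading "50% or more"
#' inclusively. The result is the crowd's binary best estimate of affected
#' skin for the image.
#'
#' @param demarcations non-empty list of [demarcation()]s for one image.
#' @param threshold vote fraction required for inclusion, in `(0, 1]`.
#' @param crowd_name label stored on the result.
#' @return list of class `consensus_mask` with fields `image_id`,
#'   `crowd_name`, `n_raters`, `mask`.
#' @export
majority_vote <- function(demarcations, threshold = 0.5, crowd_name = "crowd") {
  if (threshold <= 0 || threshold > 1) stop_cm("threshold must be in (0, 1]")
  vc <- vote_counts(demarcations)
  mask <- vc$counts / vc$n_raters >= threshold - 1e-9
  structure(
    list(
      image_id = vc$image_id, crowd_name = as.character(crowd_name),
      n_raters = vc$n_raters, mask = mask
    ),
    class = "consensus_mask"
  )
}

#' Specify a crowd-assembly rule
#'
#' Either the first `first_r` demarcations (by submission order) from one
#' feedback arm, or the `top_k` most reliable available raters of the arm
#' (reliability scored on the ground-truth-provided set, see
#' [track_rater_performance()]).
#'
#' @param name crowd label used in outputs.
#' @param arm feedback arm the crowd draws from.
#' @param first_r number of earliest demarcations to take (exclusive with
#'   `top_k`).
#' @param top_k number of best-scoring raters to take per image.
#' @return a list of class `crowd_spec`.
#' @export
crowd_spec <- function(name, arm = c("low_feedback", "high_feedback"),
                       first_r = NULL, top_k = NULL) {
  arm <- match.arg(arm)
  if (is.null(first_r) == is.null(top_k)) {
    stop_cm("exactly one of first_r or top_k must be given")
  }
  structure(
    list(
      name = as.character(name), arm = arm,
      first_r = if (!is.null(first_r)) as.integer(first_r),
      top_k = if (!is.null(top_k)) as.integer(top_k)
    ),
    class = "crowd_spec"
  )
}

#' Assemble a crowd's demarcations for one image
#'
#' In `first_r` mode, takes the `r` demarcations from the crowd's arm with
#' the smallest sequence indices (simulated arrival order), erroring if
#' fewer are available. In `top_k` mode, delegates to [select_top_k()]
#' using the supplied reliability scores. Output is ordered by
#' `sequence_index`.
#'
#' @param dataset a [study_dataset()].
#' @param image_id image to assemble for.
#' @param crowd a [crowd_spec()].
#' @param scores reliability table from [track_rater_performance()]
#'   (required in `top_k` mode).
#' @return list of [demarcation()]s.
#' @export
assemble_crowd <- function(dataset, image_id, crowd, scores = NULL) {
  ds <- image_demarcations(dataset, image_id, arm = crowd$arm)
  if (!is.null(crowd$first_r)) {
    if (length(ds) < crowd$first_r) {
      stop_cm(sprintf(
        "image %s has only %d demarcations in arm %s; crowd %s needs %d",
        image_id, length(ds), crowd$arm, crowd$name, crowd$first_r
      ))
    }
    return(ds[seq_len(crowd$first_r)])
  }
  if (is.null(scores)) stop_cm("top_k crowds need a rater score table")
  select_top_k(ds, scores, crowd$top_k)
}
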