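#' Track per-rater performance on the ground-truth-provided set
#'
#' For each rater, averages the chosen agreement metric over all of their
#' demarcations of ground-truth-provided images — the only images for which
#' the expert answer may be used for scoring without contaminating the
#' evaluation set. Raters with no such demarcation are flagged unscored.
#'
#' @param dataset a [study_dataset()].
#' @param metric_name `"mean_dice"` (higher is better) or `"mean_sae"`
#'   (mean surface-area error, lower is better).
#' @return data frame with columns rater_id, metric_name, value, n_scored,
#'   unscored, enrollment_order.
#' @export
track_rater_performance <- function(dataset, metric_name = c("mean_dice", "mean_sae")) {
  metric_name <- match.arg(metric_name)
  split_of <- vapply(dataset$images, function(x) x$split, character(1))
  if (!any(split_of == "gt_provided")) {
    stop_cm("dataset has no gt_provided images to score raters on")
  }
  acc <- new.env(parent = emptyenv())
  for (d in dataset$demarcations) {
    if (split_of[[d$image_id]] != "gt_provided") next
    im <- dataset$images[[d$image_id]]
    v <- if (metric_name == "mean_dice") {
      dice(d$mask, im$gt_affected)
    } else {
      surface_area_error(d$mask, im$gt_affected, im$skin_mask)
    }
    prev <- get0(d$rater_id, envir = acc, ifnotfound = c(0, 0))
    assign(d$rater_id, prev + c(v, 1), envir = acc)
  }
  do.call(rbind, lapply(dataset$raters, function(r) {
    s <- get0(r$rater_id, envir = acc, ifnotfound = NULL)
    data.frame(
      rater_id = r$rater_id, metric_name = metric_name,
      value = if (is.null(s)) NA_real_ else s[1] / s[2],
      n_scored = if (is.null(s)) 0L else as.integer(s[2]),
      unscored = is.null(s),
      enrollment_order = r$enrollment_order,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
}

#' Select the top-k most reliable raters' demarcations for one image
#'
#' Ranks the raters behind the supplied demarcations by their reliability
#' score (highest mean Dice, or lowest mean surface-area error), breaking
#' ties by smaller enrollment order; unscored raters rank last. Returns the
#' best `k` demarcations ordered by sequence index; if fewer than `k` are
#' available, all are returned with a warning.
#'
#' @param demarcations non-empty list of [demarcation()]s for one image.
#' @param scores table from [track_rater_performance()].
#' @param k number of raters to keep (>= 1).
#' @return list of [demarcation()]s.
#' @export
select_top_k <- function(demarcations, scores, k) {
  if (length(demarcations) == 0) stop_cm("select_top_k needs at least one demarcation")
  k <- as.integer(k)
  if (k < 1) stop_cm("k must be >= 1")
  ids <- unique(vapply(demarcations, function(d) d$image_id, character(1)))
  if (length(ids) != 1) stop_cm("demarcations mix image_ids")
  rids <- vapply(demarcations, function(d) d$rater_id, character(1))
  row <- match(rids, scores$rater_id)
  if (anyNA(row)) stop_cm("score table is missing raters: ",
                          paste(rids[is.na(row)], collapse = ", "))
  value <- scores$value[row]
  unscored <- scores$unscored[row]
  enrol <- scores$enrollment_order[row]
  higher_better <- scores$metric_name[row[1]] == "mean_dice"
  key <- ifelse(unscored, NA_real_, if (higher_better) -value else value)
  ord <- order(key, enrol, na.last = TRUE)
  if (length(demarcations) < k) {
    warning(sprintf(
      "image %s: only %d demarcations available for top-%d selection",
      ids, length(demarcations), k
    ), call. = FALSE)
    k <- length(demarcations)
  }
  chosen <- demarcations[ord[seq_len(k)]]
  chosen[order(vapply(chosen, function(d) d$sequence_index, integer(1)))]
}

#' Per-rater learning curves over affected evaluation images
#'
#' Tracks each rater's error over the first `horizon` affected,
#' ground-truth-withheld images they marked, in their own submission order,
#' binned into windows of `window` images. Raters with fewer than `horizon`
#' qualifying demarcations are excluded.
#'
#' @param dataset a [study_dataset()].
#' @param window bin width in images (must divide `horizon`).
#' @param horizon number of first qualifying images tracked per rater.
#' @param metric_name `"sae"` (surface-area error, default) or `"dice"`.
#' @return data frame with columns rater_id, bin_start, bin_end,
#'   mean_error; zero rows if no rater qualifies.
#' @export
learning_curve <- function(dataset, window = 20L, horizon = 100L,
                           metric_name = c("sae", "dice")) {
  metric_name <- match.arg(metric_name)
  window <- as.integer(window)
  horizon <- as.integer(horizon)
  if (window > horizon) stop_cm("window must not exceed horizon")
  if (horizon %% window != 0) stop_cm("window must divide horizon")
  qualifies <- vapply(dataset$images, function(im) {
    im$split == "gt_withheld" && mask_area(im$gt_affected) > 0
  }, logical(1))
  rows <- list()
  rids <- vapply(dataset$demarcations, function(d) d$rater_id, character(1))
  for (rid in names(dataset$raters)) {
    ds <- dataset$demarcations[rids == rid]
    ds <- Filter(function(d) qualifies[[d$image_id]], ds)
    if (length(ds) < horizon) next
    ds <- ds[order(vapply(ds, function(d) d$rater_seq, integer(1)))]
    ds <- ds[seq_len(horizon)]
    err <- vapply(ds, function(d) {
      im <- dataset$images[[d$image_id]]
      if (metric_name == "sae") {
        surface_area_error(d$mask, im$gt_affected, im$skin_mask)
      } else {
        dice(d$mask, im$gt_affected)
      }
    }, numeric(1))
    for (b in seq_len(horizon %/% window)) {
      lo <- (b - 1L) * window + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        rater_id = rid, bin_start = lo, bin_end = b * window,
        mean_error = mean(err[lo:(b * window)]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      rater_id = character(0), bin_start = integer(0),
      bin_end = integer(0), mean_error = numeric(0)
    )
  }
}
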