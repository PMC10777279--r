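#' Summarize a crowd's per-image agreement scores
#'
#' Medians, IQRs (25th/75th percentiles with linear interpolation between
#' order statistics) and means of Dice and surface-area error over all of a
#' crowd's scored images.
#'
#' @param scores data frame of per-image scores (as from [score_image()] /
#'   [run_study()]), with columns `label`, `dice`, `surface_area_error`.
#' @param crowd_name crowd to summarize (a value of `scores$label`).
#' @return one-row data frame with crowd_name, n_images, median/IQR/mean
#'   of both metrics.
#' @export
summarize_crowd <- function(scores, crowd_name) {
  rows <- scores[scores$label == crowd_name, , drop = FALSE]
  if (nrow(rows) == 0) stop_cm("no score rows for crowd ", crowd_name)
  q <- function(x, p) unname(quantile(x, p, type = 7))
  data.frame(
    crowd_name = crowd_name, n_images = nrow(rows),
    median_dice = median(rows$dice),
    iqr_dice_lo = q(rows$dice, 0.25), iqr_dice_hi = q(rows$dice, 0.75),
    mean_dice = mean(rows$dice),
    median_sae = median(rows$surface_area_error),
    iqr_sae_lo = q(rows$surface_area_error, 0.25),
    iqr_sae_hi = q(rows$surface_area_error, 0.75),
    mean_sae = mean(rows$surface_area_error),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Mann-Whitney U comparison of two crowds' score distributions
#'
#' Rank-sum test with midrank tie handling. For combined sample sizes up to
#' `exact_limit` the two-sided p-value is exact, from full enumeration of
#' all group labelings of the pooled values (so ties are handled exactly);
#' above the limit a normal approximation with the tie-corrected variance
#' is used. The reported U is the statistic of the first sample.
#'
#' @param errors_a,errors_b non-empty numeric vectors.
#' @param exact_limit switch to the normal approximation above this
#'   combined n (default 12).
#' @return list with `U`, `p_value`, and `method` ("exact" or "normal").
#' @export
compare_crowds <- function(errors_a, errors_b, exact_limit = 12) {
  if (length(errors_a) == 0 || length(errors_b) == 0) {
    stop_cm("both samples must be non-empty")
  }
  na <- length(errors_a)
  nb <- length(errors_b)
  pooled <- c(errors_a, errors_b)
  rk <- rank(pooled) # midranks
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2

  if (na + nb <= exact_limit) {
    combos <- combn(na + nb, na)
    us <- apply(combos, 2, function(idx) sum(rk[idx]) - na * (na + 1) / 2)
    p <- 2 * min(mean(us <= U + 1e-9), mean(us >= U - 1e-9))
    return(list(U = U, p_value = min(1, p), method = "exact"))
  }
  n <- na + nb
  ties <- table(pooled)
  mu <- na * nb / 2
  sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) {
    return(list(U = U, p_value = 1, method = "normal"))
  }
  z <- (U - mu) / sqrt(sig2)
  list(U = U, p_value = 2 * pnorm(-abs(z)), method = "normal")
}

#' Per-photo spread of consensus error across viewing angles
#'
#' For each photo, collects the surface-area error of every projected view,
#' and reports the per-photo median and min-max range, ordered by
#' descending median error — the per-photo picture of how consistently a
#' crowd handles the same skin seen from different angles.
#'
#' @param scores per-image score table with columns `image_id`,
#'   `surface_area_error` (typically one crowd's rows).
#' @param image_map data frame mapping `image_id` to `photo_id` and
#'   `view_label` (see [images_table()]).
#' @return list with `table` (photo_id, n_views, median_error, min_error,
#'   max_error; ordered by descending median) and `per_view` (photo_id,
#'   view_label, surface_area_error).
#' @export
photo_spread <- function(scores, image_map) {
  row <- match(scores$image_id, image_map$image_id)
  if (anyNA(row)) stop_cm("images missing from image_map: ",
                          paste(unique(scores$image_id[is.na(row)]), collapse = ", "))
  per_view <- data.frame(
    photo_id = image_map$photo_id[row],
    view_label = image_map$view_label[row],
    surface_area_error = scores$surface_area_error,
    stringsAsFactors = FALSE
  )
  tab <- do.call(rbind, lapply(split(per_view, per_view$photo_id), function(g) {
    data.frame(
      photo_id = g$photo_id[1], n_views = nrow(g),
      median_error = median(g$surface_area_error),
      min_error = min(g$surface_area_error),
      max_error = max(g$surface_area_error),
      stringsAsFactors = FALSE
    )
  }))
  tab <- tab[order(-tab$median_error), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, per_view = per_view)
}

#' Rater variability versus consensus error, per photo
#'
#' Tests whether disagreement among individual raters predicts how wrong
#' the crowd's consensus is. Per photo: x is the sample SD (n-1) of the
#' individual raters' marked surface-area fractions, pooled over the
#' photo's views averaged as configured; y is the consensus
#' surface-area error reduced over views by the median (or mean). An
#' ordinary least-squares line of y on x gives slope, intercept and R².
#'
#' @param consensus_scores per-image consensus score table (`image_id`,
#'   `surface_area_error`).
#' @param rater_fractions data frame of individual surface-area fractions
#'   (`image_id`, `rater_id`, `fraction`), e.g. from [run_study()].
#' @param image_map data frame with `image_id`, `photo_id`.
#' @param photo_reduction `"median"` (default) or `"mean"` view reduction.
#' @param sd_pooling `"per_view_mean"` (default: within-view rater SDs
#'   averaged over views — the clean inter-rater disagreement measure) or
#'   `"pooled"` (one SD over all individual fractions of the photo, which
#'   also absorbs between-view systematic differences).
#' @return list with `slope`, `intercept`, `r_squared`, `n_points`, and
#'   `points` (photo_id, sd_fraction, consensus_error).
#' @export
variability_vs_error <- function(consensus_scores, rater_fractions, image_map,
                                 photo_reduction = c("median", "mean"),
                                 sd_pooling = c("per_view_mean", "pooled")) {
  photo_reduction <- match.arg(photo_reduction)
  sd_pooling <- match.arg(sd_pooling)
  reduce <- if (photo_reduction == "median") median else mean

  photo_of <- function(ids) image_map$photo_id[match(ids, image_map$image_id)]
  y_by_photo <- tapply(
    consensus_scores$surface_area_error,
    photo_of(consensus_scores$image_id), reduce
  )
  fr <- rater_fractions
  fr$photo_id <- photo_of(fr$image_id)
  x_by_photo <- if (sd_pooling == "pooled") {
    tapply(fr$fraction, fr$photo_id, sd)
  } else {
    vapply(
      split(fr, fr$photo_id),
      function(g) mean(tapply(g$fraction, g$image_id, sd), na.rm = TRUE),
      numeric(1)
    )
  }
  photos <- intersect(names(y_by_photo), names(x_by_photo))
  pts <- data.frame(
    photo_id = photos,
    sd_fraction = as.numeric(x_by_photo[photos]),
    consensus_error = as.numeric(y_by_photo[photos]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  pts <- pts[is.finite(pts$sd_fraction) & is.finite(pts$consensus_error), , drop = FALSE]
  if (nrow(pts) < 3) {
    stop_cm("variability_vs_error needs at least 3 photos with a defined rater SD")
  }
  fit <- lm(consensus_error ~ sd_fraction, data = pts)
  ssr <- sum(residuals(fit)^2)
  sst <- sum((pts$consensus_error - mean(pts$consensus_error))^2)
  list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = if (sst == 0) 0 else 1 - ssr / sst,
    n_points = nrow(pts), points = pts
  )
}
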