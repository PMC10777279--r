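#' Generate a synthetic ground-truth skin image
#'
#' Emulates one expert-demarcated photo: a large connected skin region (a
#' smoothly wobbled ellipse covering well over half the frame) containing
#' `n_regions` smooth lesion blobs whose total area is calibrated to
#' `coverage_target` times the skin area (within a +/-30% band; blob radii
#' are iteratively rescaled after clipping to skin). Fully deterministic
#' given `seed` and the parameters.
#'
#' @param photo_id identifier of the synthetic photo.
#' @param height,width frame size in pixels (both >= 32).
#' @param n_regions number of affected regions (>= 0; 0 gives an empty
#'   ground-truth mask).
#' @param coverage_target target affected fraction of the skin area, in
#'   `[0, 0.9]`.
#' @param seed integer seed.
#' @param split study split to assign, `"gt_withheld"` or `"gt_provided"`.
#' @return a [skin_image()] with `view_label = "0_0"`.
#' @export
generate_ground_truth <- function(photo_id, height, width, n_regions,
                                  coverage_target, seed,
                                  split = c("gt_withheld", "gt_provided")) {
  split <- match.arg(split)
  height <- as.integer(height)
  width <- as.integer(width)
  if (height < 32 || width < 32) stop_cm("height and width must both be >= 32")
  if (coverage_target < 0 || coverage_target > 0.9) {
    stop_cm("coverage_target must lie in [0, 0.9]: larger targets cannot be met inside the skin area")
  }
  n_regions <- as.integer(n_regions)
  if (n_regions < 0) stop_cm("n_regions must be >= 0")

  with_local_seed(hash_stream("gt", photo_id, seed), {
    cr <- height / 2
    cc <- width / 2
    rows <- matrix(seq_len(height) - 0.5, height, width)
    cols <- matrix(rep(seq_len(width) - 0.5, each = height), height, width)
    # skin: ellipse with a low-order radial wobble, clamped so the area
    # stays comfortably above half the frame
    a <- 0.45 * height
    b <- 0.45 * width
    rho <- sqrt(((rows - cr) / a)^2 + ((cols - cc) / b)^2)
    theta <- atan2(rows - cr, cols - cc)
    amp <- rnorm(3, 0, 1)
    phase <- runif(3, 0, 2 * pi)
    wob <- 1 + 0.04 * (amp[1] * cos(2 * theta + phase[1]) +
                         amp[2] * cos(3 * theta + phase[2]) +
                         amp[3] * cos(4 * theta + phase[3]))
    wob <- pmin(pmax(wob, 0.9), 1.1)
    skin <- rho <= wob
    skin_area <- sum(skin)

    gt <- matrix(FALSE, height, width)
    if (n_regions > 0 && coverage_target > 0) {
      target_px <- coverage_target * skin_area
      r0 <- rep(sqrt(target_px / n_regions / pi), n_regions)
      # blob centres sampled from the skin interior, repelled from each other
      interior <- which(rho <= 0.62 * wob)
      if (length(interior) < n_regions) stop_cm("skin interior too small for the requested regions")
      centers <- matrix(NA_real_, n_regions, 2)
      for (k in seq_len(n_regions)) {
        for (try in 1:60) {
          pick <- interior[sample.int(length(interior), 1)]
          pr <- (pick - 1) %% height + 0.5
          pc <- (pick - 1) %/% height + 0.5
          if (k == 1) break
          dmin <- min(sqrt((centers[1:(k - 1), 1] - pr)^2 + (centers[1:(k - 1), 2] - pc)^2))
          if (dmin >= 1.4 * r0[1]) break
        }
        centers[k, ] <- c(pr, pc)
      }
      shape_amp <- matrix(rnorm(2 * n_regions, 0, 1), n_regions, 2)
      shape_phase <- matrix(runif(2 * n_regions, 0, 2 * pi), n_regions, 2)
      draw <- function(radii) {
        m <- matrix(FALSE, height, width)
        for (k in seq_len(n_regions)) {
          d <- sqrt((rows - centers[k, 1])^2 + (cols - centers[k, 2])^2)
          th <- atan2(rows - centers[k, 1], cols - centers[k, 2])
          g <- 1 + 0.2 * (shape_amp[k, 1] * cos(2 * th + shape_phase[k, 1]) +
                            shape_amp[k, 2] * cos(3 * th + shape_phase[k, 2]))
          g <- pmin(pmax(g, 0.6), 1.4)
          m <- m | (d <= radii[k] * g)
        }
        m & skin
      }
      for (it in 1:5) {
        gt <- draw(r0)
        got <- sum(gt)
        if (got >= 0.85 * target_px && got <= 1.15 * target_px) break
        scale <- sqrt(target_px / max(got, 1))
        r0 <- r0 * pmin(pmax(scale, 0.5), 2)
      }
    }
    skin_image(
      image_id = paste0(photo_id, "_0_0"), photo_id = photo_id,
      view_label = "0_0", skin_mask = skin, gt_affected = gt, split = split
    )
  })
}

#' Standard viewing-angle labels
#'
#' Angle combinations of 0, +15 and -15 degrees along the horizontal and
#' vertical axes, with the original camera view `"0_0"` first. `n = 9`
#' yields the full grid; `n = 7` drops the last two diagonal combinations.
#'
#' @param n number of views (1..9).
#' @return character vector of view labels.
#' @export
view_grid <- function(n = 9) {
  labels <- c(
    "0_0", "+15_0", "-15_0", "0_+15", "0_-15",
    "+15_+15", "-15_-15", "+15_-15", "-15_+15"
  )
  if (n < 1 || n > length(labels)) stop_cm("n must be in 1..9")
  labels[seq_len(n)]
}

#' Project a photo into multiple 2D views
#'
#' Stand-in for re-rendering a 3D skin surface from several camera angles:
#' each non-identity view applies one small rigid 2D transform (rotation up
#' to `max_rotation` degrees, integer translation up to `max_shift` pixels)
#' jointly to the skin and ground-truth masks, so all views depict the same
#' skin with consistent geometry. The `"0_0"` label is the identity view.
#'
#' @param image a [skin_image()] (the source, normally the `"0_0"` view).
#' @param view_labels non-empty character vector of labels (see
#'   [view_grid()]).
#' @param max_shift maximum translation magnitude per axis, pixels.
#' @param max_rotation maximum in-plane rotation, degrees.
#' @param seed integer seed; transforms are derived per (photo, view).
#' @return list of [skin_image()]s, one per label, sharing `photo_id`.
#' @export
project_views <- function(image, view_labels, max_shift = 2, max_rotation = 10,
                          seed = 0L) {
  if (length(view_labels) == 0) stop_cm("view_labels must be non-empty")
  h <- nrow(image$skin_mask)
  w <- ncol(image$skin_mask)
  lapply(view_labels, function(lab) {
    if (lab == image$view_label || lab == "0_0") {
      return(skin_image(
        image_id = paste0(image$photo_id, "_", lab), photo_id = image$photo_id,
        view_label = lab, skin_mask = image$skin_mask,
        gt_affected = image$gt_affected, split = image$split
      ))
    }
    with_local_seed(hash_stream("view", image$photo_id, lab, seed), {
      ang <- runif(1, -max_rotation, max_rotation) * pi / 180
      shift <- round(runif(2, -max_shift, max_shift))
      tf <- rigid_transform_masks(
        list(skin = image$skin_mask, gt = image$gt_affected), ang, shift
      )
      lost <- attr(tf, "lost_skin_fraction")
      if (lost > 0.05) {
        stop_cm(sprintf(
          "view %s of photo %s pushes %.1f%% of skin pixels out of frame",
          lab, image$photo_id, 100 * lost
        ))
      }
      skin_image(
        image_id = paste0(image$photo_id, "_", lab), photo_id = image$photo_id,
        view_label = lab, skin_mask = tf$skin, gt_affected = tf$gt & tf$skin,
        split = image$split
      )
    })
  })
}

# Apply one rigid transform (rotation `ang` about the frame centre, then
# translation `shift`) to a named list of same-shape masks, by inverse
# nearest-neighbour mapping. Attaches the fraction of true pixels of the
# first mask whose forward image falls outside the frame.
rigid_transform_masks <- function(masks, ang, shift) {
  m1 <- masks[[1]]
  h <- nrow(m1)
  w <- ncol(m1)
  cr <- h / 2
  cc <- w / 2
  rows <- matrix(seq_len(h) - 0.5, h, w)
  cols <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  # inverse map: target pixel centre -> source position
  dr <- rows - cr - shift[1]
  dc <- cols - cc - shift[2]
  sr <- cos(ang) * dr + sin(ang) * dc + cr
  sc <- -sin(ang) * dr + cos(ang) * dc + cc
  ir <- as.vector(floor(sr) + 1)
  ic <- as.vector(floor(sc) + 1)
  ok <- ir >= 1 & ir <= h & ic >= 1 & ic <= w
  idx <- cbind(pmin(pmax(ir, 1), h), pmin(pmax(ic, 1), w))
  out <- lapply(masks, function(m) {
    v <- m[idx]
    v[!ok] <- FALSE
    matrix(v, h, w)
  })
  # forward map of source skin pixels, for the loss check
  tr <- which(m1, arr.ind = TRUE)
  pr <- tr[, 1] - 0.5 - cr
  pc <- tr[, 2] - 0.5 - cc
  fr <- cos(ang) * pr - sin(ang) * pc + cr + shift[1]
  fc <- sin(ang) * pr + cos(ang) * pc + cc + shift[2]
  lost <- mean(fr < 0 | fr >= h | fc < 0 | fc >= w)
  attr(out, "lost_skin_fraction") <- lost
  out
}

#' Simulate one rater's demarcation of one image
#'
#' Noise model for nonexpert polygon tracing: each connected ground-truth
#' region is independently detected with probability
#' `region_detection_prob`; a detected region's boundary is traced,
#' resampled to at most `node_budget` nodes, and each node perturbed by
#' isotropic Gaussian jitter of SD `boundary_jitter_sigma` pixels; a
#' Poisson(`false_positive_rate`) number of spurious round blobs is added
#' inside the skin. The polygon set is rasterized (winding rule) and
#' clipped to the skin mask. The RNG stream is derived from
#' (seed, rater_id, image_id), so results do not depend on call order.
#'
#' @param image a [skin_image()].
#' @param rater a [rater_profile()].
#' @param seed integer master seed.
#' @param sequence_index,rater_seq ordering metadata stored on the result.
#' @param jitter_scale multiplier on the rater's jitter SD (used by the
#'   optional skill-drift knob; default 1).
#' @param shared_bias_sigma SD, in percentage points of skin area, of a
#'   per-(image, region) border-ambiguity bias applied identically to every
#'   rater's outline of that region (as a radial rescale about the region
#'   centroid). This models the systematic crowd-versus-expert reading of
#'   an ambiguous border — a per-view interpretation effect that plurality
#'   voting cannot average away and whose size does not scale with the
#'   lesion. Drawn from a stream hashed from (image, region, seed), so it
#'   is common across raters. Default 0: pure per-rater noise.
#' @return a [demarcation()].
#' @export
simulate_rater_demarcation <- function(image, rater, seed,
                                       sequence_index = 1L,
                                       rater_seq = NA_integer_,
                                       jitter_scale = 1,
                                       shared_bias_sigma = 0) {
  skill <- rater$skill
  h <- nrow(image$skin_mask)
  w <- ncol(image$skin_mask)
  lab <- label_components(image$gt_affected, connectivity = 4)
  k <- max(lab)
  bias <- if (k > 0 && shared_bias_sigma > 0) {
    vapply(seq_len(k), function(comp) {
      with_local_seed(
        hash_stream("bias", image$image_id, comp, seed),
        rnorm(1, 0, shared_bias_sigma)
      )
    }, numeric(1))
  } else {
    rep(0, k)
  }
  with_local_seed(hash_stream("demarc", rater$rater_id, image$image_id, seed), {
    polygons <- list()
    if (k > 0) {
      for (comp in seq_len(k)) {
        if (runif(1) >= skill$region_detection_prob) next
        reg <- lab == comp
        ctr <- which(reg, arr.ind = TRUE) - 0.5
        ctr <- colMeans(ctr)
        # shared bias: rescale so the region's area moves by ~bias[comp]
        # percentage points of skin, the crowd's common mis-reading of the
        # border; capped to keep the outline sane for tiny regions
        s <- 1
        if (bias[comp] != 0) {
          darea <- bias[comp] / 100 * mask_area(image$skin_mask)
          s <- sqrt(min(max(1 + darea / sum(reg), 0.04), 6.25))
        }
        loops <- mask_to_polygons(reg)
        for (loop in loops) {
          loop <- resample_loop(loop, skill$node_budget)
          if (s != 1) {
            loop <- cbind(ctr[1] + (loop[, 1] - ctr[1]) * s,
                          ctr[2] + (loop[, 2] - ctr[2]) * s)
          }
          sig <- skill$boundary_jitter_sigma * jitter_scale
          if (sig > 0) loop <- loop + matrix(rnorm(length(loop), 0, sig), nrow(loop), 2)
          polygons[[length(polygons) + 1L]] <- loop
        }
      }
    }
    n_fp <- rpois(1, skill$false_positive_rate)
    if (n_fp > 0) {
      skin_px <- which(image$skin_mask)
      for (i in seq_len(n_fp)) {
        pick <- skin_px[sample.int(length(skin_px), 1)]
        ctr <- c((pick - 1) %% h + 0.5, (pick - 1) %/% h + 0.5)
        rad <- runif(1, 2, 5)
        th <- seq(0, 2 * pi, length.out = 13)[-13]
        blob <- cbind(ctr[1] - rad * cos(th), ctr[2] + rad * sin(th))
        polygons[[length(polygons) + 1L]] <- ensure_outer_orientation(blob)
      }
    }
    mask <- if (length(polygons)) {
      rasterize_polygons(h, w, polygons) & image$skin_mask
    } else {
      matrix(FALSE, h, w)
    }
    demarcation(
      rater_id = rater$rater_id, image_id = image$image_id,
      polygons = polygons, mask = mask, sequence_index = sequence_index,
      skin_mask = image$skin_mask, rater_seq = rater_seq
    )
  })
}
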