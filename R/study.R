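#' Skill distribution for one feedback arm
#'
#' Parameters of the sampling distribution from which rater skills are
#' drawn. Boundary jitter is lognormal (coarse mobile tracing, a few pixels
#' of node noise on average); detection probability is normal truncated to
#' `[0.5, 1]`; the false-positive rate is shared; node budgets are uniform
#' integers over `node_budget_range`. Alternatively supply `skills`, a data
#' frame with one row per rater (columns boundary_jitter_sigma,
#' region_detection_prob, false_positive_rate, node_budget), to pin skills
#' exactly.
#'
#' @param jitter_meanlog,jitter_sdlog lognormal parameters of the jitter SD
#'   (pixels); the defaults give a median of 2 px.
#' @param detection_mean,detection_sd truncated-normal parameters of the
#'   per-region detection probability.
#' @param false_positive_rate expected spurious regions per image.
#' @param node_budget_range integer range of per-polygon node budgets.
#' @param skills optional explicit per-rater skill data frame (overrides
#'   the distribution).
#' @return a list of class `skill_distribution`.
#' @export
skill_distribution <- function(jitter_meanlog = log(2), jitter_sdlog = 0.4,
                               detection_mean = 0.9, detection_sd = 0.05,
                               false_positive_rate = 0.1,
                               node_budget_range = c(12L, 40L),
                               skills = NULL) {
  structure(
    list(
      jitter_meanlog = jitter_meanlog, jitter_sdlog = jitter_sdlog,
      detection_mean = detection_mean, detection_sd = detection_sd,
      false_positive_rate = false_positive_rate,
      node_budget_range = as.integer(node_budget_range),
      skills = skills
    ),
    class = "skill_distribution"
  )
}

sample_arm_skills <- function(dist, n, jitter_multiplier = 1) {
  if (!is.null(dist$skills)) {
    sk <- dist$skills
    if (nrow(sk) < n) stop_cm("explicit skills table has fewer rows than raters in the arm")
    return(sk[seq_len(n), , drop = FALSE])
  }
  jit <- rlnorm(n, dist$jitter_meanlog, dist$jitter_sdlog) * jitter_multiplier
  det <- pmin(pmax(rnorm(n, dist$detection_mean, dist$detection_sd), 0.5), 1)
  nb <- sample(seq(dist$node_budget_range[1], dist$node_budget_range[2]), n, replace = TRUE)
  data.frame(
    boundary_jitter_sigma = jit, region_detection_prob = det,
    false_positive_rate = rep(dist$false_positive_rate, n),
    node_budget = as.integer(nb)
  )
}

#' Study configuration
#'
#' Assembles and validates the configuration consumed by
#' [simulate_study()]. The split structure mirrors the original study
#' design: a ground-truth-provided set (feedback/training, 7 views per
#' photo) and a ground-truth-withheld set (evaluation, 9 views per photo),
#' affected and unaffected photos in each, and two feedback arms with
#' exposure rates 1/4 (high) and 1/14 (low). Photo counts default to a
#' desk-scale study; `preset = "study"` installs the original geometry
#' (100 + 20 provided photos at 7 views, 79 + 161 withheld photos at 9
#' views, i.e. 3000 2D images of which 711 are withheld affected) with
#' zero demarcations per image, for structural arithmetic.
#'
#' @param height,width image size in pixels.
#' @param gt_provided,gt_withheld per-split settings: lists with
#'   `affected_photos`, `unaffected_photos`, `n_views`.
#' @param lesions list with `n_regions` (integer range) and `coverage`
#'   (affected-fraction range) for affected photos.
#' @param view_transform list with `max_shift` (px) and `max_rotation`
#'   (degrees) for non-identity views.
#' @param arms named list (`high_feedback`, `low_feedback`) of lists with
#'   `n_raters`, `feedback_rate`, `demarcations_per_image`, `skill`
#'   (a [skill_distribution()]), and optional `jitter_multiplier`.
#' @param crowds named list of [crowd_spec()]s evaluated by [run_study()].
#' @param consensus_threshold vote fraction for consensus inclusion
#'   (study-faithful value 0.5, pixels at exactly the threshold included).
#' @param ranking_metric metric ranking raters for top-k crowds,
#'   `"mean_dice"` or `"mean_sae"`.
#' @param photo_reduction reduction of per-view consensus errors to one
#'   per-photo value, `"median"` or `"mean"`.
#' @param sd_pooling how rater surface-area SDs are formed per photo:
#'   `"pooled"` across all views or `"per_view_mean"`.
#' @param shared_bias_sigma SD, in percentage points of skin area, of the
#'   per-(image, region) border bias shared by all raters (see
#'   [simulate_rater_demarcation()]); the systematic component of crowd
#'   error that voting cannot remove.
#' @param skill_drift per-submission multiplicative drift of jitter
#'   (0 = time-constant skill, the default; negative values emulate
#'   learning, for testing the learning-curve machinery).
#' @param preset `NULL` or `"study"`.
#' @return a list of class `study_config` with all defaults materialized.
#' @export
study_config <- function(height = 64, width = 64,
                         gt_provided = list(affected_photos = 4, unaffected_photos = 1, n_views = 7),
                         gt_withheld = list(affected_photos = 3, unaffected_photos = 2, n_views = 9),
                         lesions = list(n_regions = c(1L, 3L), coverage = c(0.05, 0.25)),
                         view_transform = list(max_shift = 2, max_rotation = 10),
                         arms = list(
                           high_feedback = list(
                             n_raters = 20, feedback_rate = 1 / 4,
                             demarcations_per_image = 17, skill = skill_distribution()
                           ),
                           low_feedback = list(
                             n_raters = 40, feedback_rate = 1 / 14,
                             demarcations_per_image = 35, skill = skill_distribution()
                           )
                         ),
                         crowds = default_crowds(),
                         consensus_threshold = 0.5,
                         ranking_metric = c("mean_dice", "mean_sae"),
                         photo_reduction = c("median", "mean"),
                         sd_pooling = c("per_view_mean", "pooled"),
                         shared_bias_sigma = 3,
                         skill_drift = 0,
                         preset = NULL) {
  ranking_metric <- match.arg(ranking_metric)
  photo_reduction <- match.arg(photo_reduction)
  sd_pooling <- match.arg(sd_pooling)
  if (!is.null(preset)) {
    preset <- match.arg(preset, "study")
    gt_provided <- list(affected_photos = 100, unaffected_photos = 20, n_views = 7)
    gt_withheld <- list(affected_photos = 79, unaffected_photos = 161, n_views = 9)
    arms <- lapply(arms, function(a) {
      a$demarcations_per_image <- 0
      a
    })
  }
  cfg <- list(
    height = as.integer(height), width = as.integer(width),
    gt_provided = gt_provided, gt_withheld = gt_withheld,
    lesions = lesions, view_transform = view_transform, arms = arms,
    crowds = crowds, consensus_threshold = consensus_threshold,
    ranking_metric = ranking_metric, photo_reduction = photo_reduction,
    sd_pooling = sd_pooling, shared_bias_sigma = shared_bias_sigma,
    skill_drift = skill_drift
  )
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  bad <- character(0)
  if (cfg$height < 32 || cfg$width < 32) bad <- c(bad, "height/width must be >= 32")
  for (s in c("gt_provided", "gt_withheld")) {
    sp <- cfg[[s]]
    if (!all(c("affected_photos", "unaffected_photos", "n_views") %in% names(sp))) {
      bad <- c(bad, paste0(s, ": needs affected_photos, unaffected_photos, n_views"))
    } else if (sp$n_views < 1 || sp$n_views > 9) {
      bad <- c(bad, paste0(s, ": n_views must be in 1..9"))
    }
  }
  if (!all(c("high_feedback", "low_feedback") %in% names(cfg$arms))) {
    bad <- c(bad, "arms must include high_feedback and low_feedback")
  }
  for (a in names(cfg$arms)) {
    arm <- cfg$arms[[a]]
    if (arm$feedback_rate <= 0 || arm$feedback_rate > 1) {
      bad <- c(bad, paste0(a, ": feedback_rate must be in (0, 1]"))
    }
    if (arm$demarcations_per_image > arm$n_raters) {
      bad <- c(bad, paste0(a, ": demarcations_per_image exceeds n_raters (quota infeasible)"))
    }
  }
  for (cw in cfg$crowds) {
    if (!cw$arm %in% names(cfg$arms)) {
      bad <- c(bad, paste0("crowd ", cw$name, " references unknown arm ", cw$arm))
    }
  }
  if (cfg$consensus_threshold <= 0 || cfg$consensus_threshold > 1) {
    bad <- c(bad, "consensus_threshold must be in (0, 1]")
  }
  if (length(bad)) stop_cm("invalid study config:\n  - ", paste(bad, collapse = "\n  - "))
  invisible(cfg)
}

#' The study's four crowd definitions
#'
#' First 17 raters of the high arm, first 17 and first 32 of the low arm,
#' and the per-image 5 most reliable raters of the low arm.
#'
#' @return named list of [crowd_spec()]s.
#' @export
default_crowds <- function() {
  list(
    high_r17 = crowd_spec("high_r17", "high_feedback", first_r = 17),
    low_r17 = crowd_spec("low_r17", "low_feedback", first_r = 17),
    low_r32 = crowd_spec("low_r32", "low_feedback", first_r = 32),
    low_top5 = crowd_spec("low_top5", "low_feedback", top_k = 5)
  )
}

#' Simulate a complete crowd study
#'
#' Generates photos and their projected views per split, samples rater
#' pools for both feedback arms, assigns raters to images, simulates every
#' demarcation, and logs feedback exposure (each rater "sees" the expert
#' answer on every `1/feedback_rate`-th of their ground-truth-provided
#' submissions). Fully deterministic given `config` and `seed`; individual
#' demarcations use RNG streams hashed from (seed, rater, image) and are
#' therefore independent of generation order.
#'
#' @param config a [study_config()].
#' @param seed integer master seed.
#' @return a [study_dataset()].
#' @export
simulate_study <- function(config, seed) {
  validate_study_config(config)
  with_local_seed(hash_stream("study", seed), {
    # --- images -----------------------------------------------------------
    images <- list()
    photo_no <- 0
    for (s in c("gt_provided", "gt_withheld")) {
      sp <- config[[s]]
      n_photos <- sp$affected_photos + sp$unaffected_photos
      affected <- rep(c(TRUE, FALSE), c(sp$affected_photos, sp$unaffected_photos))
      for (i in seq_len(n_photos)) {
        photo_no <- photo_no + 1
        pid <- sprintf("P%03d", photo_no)
        nr <- if (affected[i]) sample(seq(config$lesions$n_regions[1], config$lesions$n_regions[2]), 1) else 0L
        cov <- if (affected[i]) runif(1, config$lesions$coverage[1], config$lesions$coverage[2]) else 0
        base <- generate_ground_truth(
          pid, config$height, config$width, nr, cov,
          seed = seed, split = s
        )
        views <- project_views(
          base, view_grid(sp$n_views),
          max_shift = config$view_transform$max_shift,
          max_rotation = config$view_transform$max_rotation, seed = seed
        )
        images <- c(images, views)
      }
    }
    names(images) <- vapply(images, function(x) x$image_id, character(1))

    # --- raters -----------------------------------------------------------
    raters <- list()
    for (a in names(config$arms)) {
      arm <- config$arms[[a]]
      if (arm$n_raters == 0) next
      sk <- sample_arm_skills(arm$skill, arm$n_raters, arm$jitter_multiplier %||% 1)
      for (i in seq_len(arm$n_raters)) {
        rid <- sprintf("%s_R%03d", if (a == "high_feedback") "H" else "L", i)
        raters[[rid]] <- rater_profile(
          rid, arm = a, enrollment_order = 1L, # reassigned below
          boundary_jitter_sigma = sk$boundary_jitter_sigma[i],
          region_detection_prob = sk$region_detection_prob[i],
          false_positive_rate = sk$false_positive_rate[i],
          node_budget = sk$node_budget[i]
        )
      }
    }
    if (length(raters)) {
      enr <- sample.int(length(raters))
      for (i in seq_along(raters)) raters[[i]]$enrollment_order <- enr[i]
    }

    # --- assignment -------------------------------------------------------
    arm_of <- vapply(raters, function(r) r$arm, character(1))
    assign_rows <- list()
    for (img in images) {
      picked <- character(0)
      for (a in names(config$arms)) {
        quota <- config$arms[[a]]$demarcations_per_image
        if (quota == 0) next
        pool <- names(raters)[arm_of == a]
        if (length(pool) < quota) {
          stop_cm("quota infeasible: arm ", a, " has ", length(pool),
                  " raters but needs ", quota, " per image")
        }
        picked <- c(picked, pool[sample.int(length(pool), quota)])
      }
      if (length(picked)) {
        seqix <- sample.int(length(picked)) # simulated arrival order
        assign_rows[[length(assign_rows) + 1L]] <- data.frame(
          rater_id = picked, image_id = img$image_id, sequence_index = seqix,
          stringsAsFactors = FALSE
        )
      }
    }
    assign <- if (length(assign_rows)) do.call(rbind, assign_rows) else
      data.frame(rater_id = character(0), image_id = character(0),
                 sequence_index = integer(0))

    # per-rater chronological stream (order in which the rater worked)
    assign$rater_seq <- integer(nrow(assign))
    for (rid in unique(assign$rater_id)) {
      idx <- which(assign$rater_id == rid)
      assign$rater_seq[idx] <- sample.int(length(idx))
    }

    # --- demarcations -----------------------------------------------------
    demarcations <- vector("list", nrow(assign))
    if (nrow(assign)) {
      for (i in seq_len(nrow(assign))) {
        r <- raters[[assign$rater_id[i]]]
        jscale <- max(0, 1 + config$skill_drift * (assign$rater_seq[i] - 1))
        demarcations[[i]] <- simulate_rater_demarcation(
          images[[assign$image_id[i]]], r, seed,
          sequence_index = assign$sequence_index[i],
          rater_seq = assign$rater_seq[i],
          jitter_scale = jscale,
          shared_bias_sigma = config$shared_bias_sigma %||% 0
        )
      }
    }

    # --- feedback exposure log -------------------------------------------
    split_of <- vapply(images, function(x) x$split, character(1))
    exposure <- NULL
    if (nrow(assign)) {
      prov <- assign[split_of[assign$image_id] == "gt_provided", , drop = FALSE]
      rows <- list()
      for (rid in unique(prov$rater_id)) {
        sub <- prov[prov$rater_id == rid, , drop = FALSE]
        sub <- sub[order(sub$rater_seq), , drop = FALSE]
        every <- max(1L, round(1 / config$arms[[raters[[rid]]$arm]]$feedback_rate))
        keep <- seq_len(nrow(sub)) %% every == 1L %% every
        if (any(keep)) {
          rows[[length(rows) + 1L]] <- data.frame(
            rater_id = rid, image_id = sub$image_id[keep],
            rater_seq = sub$rater_seq[keep], stringsAsFactors = FALSE
          )
        }
      }
      exposure <- if (length(rows)) do.call(rbind, rows) else NULL
    }

    study_dataset(
      images = images, raters = raters, demarcations = demarcations,
      exposure = exposure, config_echo = config
    )
  })
}
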