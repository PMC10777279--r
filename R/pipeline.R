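#' Run the full crowd analysis on a study dataset
#'
#' For every configured crowd and every evaluation image (by default the
#' ground-truth-withheld images with affected skin, mirroring the original
#' analysis scope), assembles the crowd, builds the plurality-vote
#' consensus mask, and scores it against ground truth; then computes rater
#' reliability scores, crowd summaries, pairwise Mann-Whitney comparisons,
#' per-photo view spread, variability-versus-error regressions, and
#' learning curves.
#'
#' @param dataset a [study_dataset()].
#' @param crowds named list of [crowd_spec()]s; defaults to the dataset
#'   config's crowds (or [default_crowds()]).
#' @param eval_split split evaluated (`"gt_withheld"` default).
#' @param affected_only restrict evaluation to images with affected skin
#'   per ground truth (default `TRUE`).
#' @param learning_window,learning_horizon learning-curve binning
#'   (defaults 20 and 100 images).
#' @return list with data frames `scores`, `rater_scores`, `summary`,
#'   `comparisons`, `photo_spread`, `regression`, `regression_points`,
#'   `learning_curve`, and `rater_fractions`, plus `consensus` (list of
#'   consensus masks keyed crowd/image).
#' @export
run_study <- function(dataset, crowds = NULL,
                      eval_split = "gt_withheld", affected_only = TRUE,
                      learning_window = 20L, learning_horizon = 100L) {
  cfg <- dataset$config_echo
  has_cfg <- inherits(cfg, "study_config")
  if (is.null(crowds)) {
    crowds <- if (has_cfg) cfg$crowds else default_crowds()
  }
  threshold <- if (has_cfg) cfg$consensus_threshold else 0.5
  ranking_metric <- if (has_cfg) cfg$ranking_metric else "mean_dice"
  photo_reduction <- if (has_cfg) cfg$photo_reduction else "median"
  sd_pooling <- if (has_cfg) cfg$sd_pooling else "per_view_mean"

  imap <- images_table(dataset)
  eval_ids <- imap$image_id[imap$split == eval_split &
                              (!affected_only | imap$affected)]
  if (length(eval_ids) == 0) stop_cm("no images in the evaluation scope")

  has_provided <- any(vapply(dataset$images, function(x) x$split == "gt_provided", logical(1)))
  rater_scores <- if (has_provided) {
    rbind(
      track_rater_performance(dataset, "mean_dice"),
      track_rater_performance(dataset, "mean_sae")
    )
  } else {
    # no scoring set: every rater is explicitly unscored
    do.call(rbind, lapply(dataset$raters, function(r) {
      data.frame(
        rater_id = r$rater_id,
        metric_name = c("mean_dice", "mean_sae"), value = NA_real_,
        n_scored = 0L, unscored = TRUE, enrollment_order = r$enrollment_order,
        stringsAsFactors = FALSE, row.names = NULL
      )
    }))
  }
  ranking <- rater_scores[rater_scores$metric_name == ranking_metric, , drop = FALSE]

  scores <- list()
  fractions <- list()
  consensus <- list()
  for (cw in crowds) {
    for (id in eval_ids) {
      ds <- assemble_crowd(dataset, id, cw, scores = ranking)
      cm <- majority_vote(ds, threshold = threshold, crowd_name = cw$name)
      consensus[[paste(cw$name, id, sep = "/")]] <- cm
      im <- dataset$images[[id]]
      scores[[length(scores) + 1L]] <- score_image(cm$mask, im, label = cw$name)
      fractions[[length(fractions) + 1L]] <- data.frame(
        crowd_name = cw$name, image_id = id,
        rater_id = vapply(ds, function(d) d$rater_id, character(1)),
        fraction = vapply(ds, function(d) {
          surface_area_fraction(d$mask, im$skin_mask)
        }, numeric(1)),
        stringsAsFactors = FALSE
      )
    }
  }
  scores <- do.call(rbind, scores)
  fractions <- do.call(rbind, fractions)

  summary <- do.call(rbind, lapply(crowds, function(cw) summarize_crowd(scores, cw$name)))
  rownames(summary) <- NULL

  crowd_names <- vapply(crowds, function(cw) cw$name, character(1))
  comparisons <- list()
  if (length(crowd_names) > 1) {
    for (i in seq_len(length(crowd_names) - 1)) {
      for (j in (i + 1):length(crowd_names)) {
        for (metric in c("dice", "surface_area_error")) {
          a <- scores[[metric]][scores$label == crowd_names[i]]
          b <- scores[[metric]][scores$label == crowd_names[j]]
          cmp <- compare_crowds(a, b)
          comparisons[[length(comparisons) + 1L]] <- data.frame(
            crowd_a = crowd_names[i], crowd_b = crowd_names[j], metric = metric,
            U = cmp$U, p_value = cmp$p_value, method = cmp$method,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else NULL

  spread <- do.call(rbind, lapply(crowd_names, function(nm) {
    sp <- photo_spread(scores[scores$label == nm, , drop = FALSE], imap)$table
    cbind(crowd_name = nm, sp, stringsAsFactors = FALSE)
  }))
  rownames(spread) <- NULL

  regression <- list()
  reg_points <- list()
  for (nm in crowd_names) {
    # infeasible for < 3 photos or single-rater crowds (no within-crowd SD)
    ve <- tryCatch(
      variability_vs_error(
        scores[scores$label == nm, , drop = FALSE],
        setNames(
          fractions[fractions$crowd_name == nm, c("image_id", "rater_id", "fraction")],
          c("image_id", "rater_id", "fraction")
        ),
        imap, photo_reduction = photo_reduction, sd_pooling = sd_pooling
      ),
      error = function(e) NULL
    )
    if (is.null(ve)) next
    regression[[length(regression) + 1L]] <- data.frame(
      crowd_name = nm, slope = ve$slope, intercept = ve$intercept,
      r_squared = ve$r_squared, n_points = ve$n_points,
      stringsAsFactors = FALSE
    )
    reg_points[[length(reg_points) + 1L]] <- cbind(
      crowd_name = nm, ve$points, stringsAsFactors = FALSE
    )
  }
  regression <- if (length(regression)) do.call(rbind, regression) else NULL
  reg_points <- if (length(reg_points)) do.call(rbind, reg_points) else NULL

  lc <- learning_curve(dataset, window = learning_window, horizon = learning_horizon)

  list(
    scores = scores, rater_scores = rater_scores, summary = summary,
    comparisons = comparisons, photo_spread = spread,
    regression = regression, regression_points = reg_points,
    learning_curve = lc, rater_fractions = fractions, consensus = consensus
  )
}

#' Simulate a study and write it to disk
#'
#' @param config a [study_config()], or the path of a JSON config file.
#' @param out_dir output directory (parent must exist).
#' @param seed integer master seed.
#' @return the simulated [study_dataset()], invisibly.
#' @export
cmd_simulate <- function(config, out_dir, seed = 42L) {
  if (is.character(config)) config <- read_study_config(config)
  dataset <- simulate_study(config, seed = seed)
  dataset$config_echo$master_seed <- as.integer(seed)
  write_study_dataset(dataset, out_dir)
  invisible(dataset)
}

#' Run the analysis on a stored dataset and write all outputs
#'
#' Reads a dataset written by [cmd_simulate()] / [write_study_dataset()],
#' runs [run_study()], and writes `scores.csv`, `rater_scores.csv`,
#' `summary.csv`, `comparisons.csv`, `photo_spread.csv`, `regression.csv`,
#' `learning_curve.csv`, consensus masks as PNG, and `run_log.txt`
#' (config hash, seed, versions).
#'
#' @param data_dir dataset directory.
#' @param out_dir output directory (parent must exist).
#' @param crowds optional crowd-name subset to evaluate.
#' @param write_consensus_masks write consensus PNG masks (default `TRUE`).
#' @return the [run_study()] result list, invisibly.
#' @export
cmd_run_study <- function(data_dir, out_dir, crowds = NULL,
                          write_consensus_masks = TRUE) {
  dataset <- read_study_dataset(data_dir)
  cw <- NULL
  if (!is.null(crowds)) {
    all_cw <- if (inherits(dataset$config_echo, "study_config")) {
      dataset$config_echo$crowds
    } else {
      default_crowds()
    }
    missing <- setdiff(crowds, names(all_cw))
    if (length(missing)) stop_cm("unknown crowds: ", paste(missing, collapse = ", "))
    cw <- all_cw[crowds]
  }
  res <- run_study(dataset, crowds = cw)

  parent <- dirname(normalizePath(out_dir, mustWork = FALSE))
  if (!dir.exists(parent)) stop_cm("parent directory does not exist: ", parent)
  if (!dir.exists(out_dir)) dir.create(out_dir)
  wr <- function(df, name) {
    if (!is.null(df)) write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(res$scores, "scores.csv")
  wr(res$rater_scores, "rater_scores.csv")
  wr(res$summary, "summary.csv")
  wr(res$comparisons, "comparisons.csv")
  wr(res$photo_spread, "photo_spread.csv")
  wr(res$regression, "regression.csv")
  wr(res$learning_curve, "learning_curve.csv")
  if (write_consensus_masks) {
    dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
    for (cm in res$consensus) {
      write_mask_png(cm$mask, file.path(
        out_dir, "masks", paste0(cm$image_id, ".consensus_", cm$crowd_name, ".png")
      ))
    }
  }
  cfg <- dataset$config_echo
  cfg_json <- jsonlite::toJSON(unclass_config(cfg), auto_unbox = TRUE, digits = NA)
  writeLines(c(
    paste0("config_hash: ", hash_stream(as.character(cfg_json))),
    paste0("master_seed: ", if (!is.null(cfg$master_seed)) cfg$master_seed else "NA"),
    paste0("package: crowdmark ", as.character(utils::packageVersion("crowdmark"))),
    paste0("r_version: ", R.version.string)
  ), file.path(out_dir, "run_log.txt"))
  invisible(res)
}
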