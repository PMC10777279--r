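# Small constructed fixtures for consensus / reliability / analysis tests.

demarc_from_mask <- function(mask, rater = "R1", image = "I1", seqix = 1L,
                             skin = NULL, rater_seq = NA_integer_) {
  demarcation(
    rater_id = rater, image_id = image,
    polygons = mask_to_polygons(mask), mask = mask,
    sequence_index = seqix, skin_mask = skin, rater_seq = rater_seq
  )
}

# A hand-built dataset: `n_images` all-skin 10x10 images (half gt_provided,
# rest gt_withheld; gt = a 4x4 block), raters given as a data frame
# (rater_id, arm), and a demarcation of every image by every rater using the
# mask returned by mask_fun(rater_id, image_id).
tiny_dataset <- function(raters_df, n_images, mask_fun,
                         splits = NULL, gt_masks = NULL) {
  skin <- matrix(TRUE, 10, 10)
  default_gt <- matrix(FALSE, 10, 10)
  default_gt[3:6, 3:6] <- TRUE
  splits <- splits %||% rep(c("gt_provided", "gt_withheld"), length.out = n_images)
  images <- lapply(seq_len(n_images), function(i) {
    skin_image(
      image_id = sprintf("I%02d", i), photo_id = sprintf("P%02d", (i + 1) %/% 2),
      view_label = if (i %% 2 == 1) "0_0" else "+15_0",
      skin_mask = skin,
      gt_affected = if (is.null(gt_masks)) default_gt else gt_masks[[i]],
      split = splits[i]
    )
  })
  raters <- lapply(seq_len(nrow(raters_df)), function(i) {
    rater_profile(raters_df$rater_id[i], arm = raters_df$arm[i], enrollment_order = i)
  })
  demarcations <- list()
  for (i in seq_len(n_images)) {
    iid <- sprintf("I%02d", i)
    for (k in seq_len(nrow(raters_df))) {
      demarcations[[length(demarcations) + 1L]] <- demarc_from_mask(
        mask_fun(raters_df$rater_id[k], iid),
        rater = raters_df$rater_id[k], image = iid, seqix = k,
        skin = skin, rater_seq = i
      )
    }
  }
  study_dataset(images, raters, demarcations)
}

# Simulated low-feedback pool: 5 low-jitter + 12 high-jitter raters, used by
# the top-k recovery checks. Returns the dataset; provided images are the
# scoring set, withheld images the evaluation set.
pool_dataset <- function(seed, n_provided_photos = 10, n_withheld_photos = 4,
                         provided_views = 3, withheld_views = 1,
                         sigma_good = 1, sigma_bad = 6) {
  skills <- data.frame(
    boundary_jitter_sigma = c(rep(sigma_good, 5), rep(sigma_bad, 12)),
    region_detection_prob = 1,
    false_positive_rate = 0,
    node_budget = 24L
  )
  cfg <- study_config(
    height = 48, width = 48,
    gt_provided = list(affected_photos = n_provided_photos, unaffected_photos = 0,
                       n_views = provided_views),
    gt_withheld = list(affected_photos = n_withheld_photos, unaffected_photos = 0,
                       n_views = withheld_views),
    arms = list(
      high_feedback = list(n_raters = 0, feedback_rate = 1 / 4,
                           demarcations_per_image = 0, skill = skill_distribution()),
      low_feedback = list(n_raters = 17, feedback_rate = 1 / 14,
                          demarcations_per_image = 17,
                          skill = skill_distribution(skills = skills))
    ),
    crowds = list(
      low_r17 = crowd_spec("low_r17", "low_feedback", first_r = 17),
      low_top5 = crowd_spec("low_top5", "low_feedback", top_k = 5)
    )
  )
  simulate_study(cfg, seed = seed)
}
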