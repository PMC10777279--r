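test_that("ground-truth generation honours its contract", {
  im <- generate_ground_truth("P1", 128, 128, 3, 0.10, seed = 7)
  frac <- mask_area(im$gt_affected) / mask_area(im$skin_mask)
  expect_gte(frac, 0.07) # within +/-30% of the 10% target
  expect_lte(frac, 0.13)
  expect_gte(mask_area(im$skin_mask), 0.5 * 128 * 128)
  expect_equal(max(label_components(im$skin_mask, 4)), 1) # one connected skin region
  expect_true(mask_subset(im$gt_affected, im$skin_mask))

  # no regions -> empty ground truth
  empty <- generate_ground_truth("P2", 64, 64, 0, 0.2, seed = 1)
  expect_equal(mask_area(empty$gt_affected), 0)

  # seeded determinism
  again <- generate_ground_truth("P1", 128, 128, 3, 0.10, seed = 7)
  expect_identical(im, again)
  other <- generate_ground_truth("P1", 128, 128, 3, 0.10, seed = 8)
  expect_false(identical(im$gt_affected, other$gt_affected))

  expect_error(generate_ground_truth("P", 16, 64, 1, 0.1, seed = 1), ">= 32")
  expect_error(generate_ground_truth("P", 64, 64, 1, 0.95, seed = 1), "0.9")
})

test_that("view projection keeps geometry consistent across angles", {
  im <- generate_ground_truth("P1", 64, 64, 2, 0.15, seed = 3)

  # zero-magnitude transforms reproduce the source exactly
  frozen <- project_views(im, view_grid(3), max_shift = 0, max_rotation = 0, seed = 5)
  for (v in frozen) {
    expect_identical(v$skin_mask, im$skin_mask)
    expect_identical(v$gt_affected, im$gt_affected)
  }

  views <- project_views(im, view_grid(9), seed = 5)
  expect_length(views, 9)
  expect_equal(unique(vapply(views, function(v) v$photo_id, character(1))), "P1")
  expect_equal(vapply(views, function(v) v$view_label, character(1)), view_grid(9))

  src_frac <- 100 * mask_area(im$gt_affected) / mask_area(im$skin_mask)
  for (v in views) {
    expect_true(mask_subset(v$gt_affected, v$skin_mask))
    frac <- 100 * mask_area(v$gt_affected) / mask_area(v$skin_mask)
    expect_lte(abs(frac - src_frac), 2) # area ratios survive resampling
  }
})

test_that("rater noise model hits its limiting behaviours", {
  im <- generate_ground_truth("P1", 64, 64, 1, 0.12, seed = 11)

  blind <- rater_profile("B", "low_feedback", 1,
    region_detection_prob = 0, false_positive_rate = 0
  )
  d0 <- simulate_rater_demarcation(im, blind, seed = 2)
  expect_equal(mask_area(d0$mask), 0)

  sharp <- rater_profile("S", "low_feedback", 2,
    boundary_jitter_sigma = 0, region_detection_prob = 1,
    false_positive_rate = 0, node_budget = 200
  )
  d1 <- simulate_rater_demarcation(im, sharp, seed = 2)
  expect_gte(dice(d1$mask, im$gt_affected), 0.95)

  # determinism in (seed, rater, image), regardless of call order
  expect_identical(d1, simulate_rater_demarcation(im, sharp, seed = 2))
  expect_true(mask_subset(d1$mask, im$skin_mask))
  noisy <- rater_profile("N", "low_feedback", 3, boundary_jitter_sigma = 2)
  dn <- simulate_rater_demarcation(im, noisy, seed = 2)
  expect_identical(dn, simulate_rater_demarcation(im, noisy, seed = 2))
  expect_false(identical(dn$mask, simulate_rater_demarcation(im, noisy, seed = 3)$mask))
})

test_that("mean rater accuracy degrades monotonically with boundary jitter", {
  im <- generate_ground_truth("P1", 48, 48, 1, 0.15, seed = 21)
  mean_dice_at <- function(sigma) {
    r <- rater_profile("R", "low_feedback", 1,
      boundary_jitter_sigma = sigma, region_detection_prob = 1,
      false_positive_rate = 0, node_budget = 24
    )
    mean(vapply(1:30, function(s) {
      dice(simulate_rater_demarcation(im, r, seed = s)$mask, im$gt_affected)
    }, numeric(1)))
  }
  d <- vapply(c(0, 2, 6), mean_dice_at, numeric(1))
  expect_gte(d[1], d[2])
  expect_gte(d[2], d[3])
})

test_that("region detection frequency is calibrated to the configured probability", {
  im <- generate_ground_truth("P1", 64, 64, 3, 0.12, seed = 31)
  k <- max(label_components(im$gt_affected, 4))
  expect_gte(k, 1)
  p <- 0.7
  r <- rater_profile("R", "low_feedback", 1,
    boundary_jitter_sigma = 0, region_detection_prob = p,
    false_positive_rate = 0, node_budget = 60
  )
  lab <- label_components(im$gt_affected, 4)
  n_sim <- 200
  detected <- 0
  for (s in seq_len(n_sim)) {
    m <- simulate_rater_demarcation(im, r, seed = s)$mask
    for (comp in seq_len(k)) {
      # a region counts as detected when most of it is marked
      reg <- lab == comp
      if (sum(m & reg) > 0.5 * sum(reg)) detected <- detected + 1
    }
  }
  expect_lte(abs(detected / (n_sim * k) - p), 0.05)
})

test_that("simulate_study satisfies quotas, ordering and determinism", {
  cfg <- study_config(
    height = 48, width = 48,
    gt_provided = list(affected_photos = 2, unaffected_photos = 1, n_views = 2),
    gt_withheld = list(affected_photos = 2, unaffected_photos = 1, n_views = 3),
    arms = list(
      high_feedback = list(n_raters = 5, feedback_rate = 1 / 4,
                           demarcations_per_image = 3, skill = skill_distribution()),
      low_feedback = list(n_raters = 6, feedback_rate = 1 / 14,
                          demarcations_per_image = 4, skill = skill_distribution())
    ),
    crowds = list(high_r3 = crowd_spec("high_r3", "high_feedback", first_r = 3))
  )
  ds <- simulate_study(cfg, seed = 17)
  it <- images_table(ds)
  expect_equal(nrow(it), 3 * 2 + 3 * 3)
  dem <- demarcations_table(ds)
  expect_equal(nrow(dem), nrow(it) * 7)
  # per-image sequence 1..n; per-arm quotas met exactly
  arm_of <- setNames(raters_table(ds)$arm, raters_table(ds)$rater_id)
  for (iid in it$image_id) {
    sub <- dem[dem$image_id == iid, ]
    expect_setequal(sub$sequence_index, seq_len(nrow(sub)))
    expect_equal(sum(arm_of[sub$rater_id] == "high_feedback"), 3)
    expect_equal(sum(arm_of[sub$rater_id] == "low_feedback"), 4)
  }
  # per-rater stream is a permutation
  for (rid in unique(dem$rater_id)) {
    expect_setequal(dem$rater_seq[dem$rater_id == rid],
                    seq_len(sum(dem$rater_id == rid)))
  }
  # every demarcation clipped to skin
  for (d in ds$demarcations) {
    expect_true(mask_subset(d$mask, ds$images[[d$image_id]]$skin_mask))
  }
  # feedback exposure: every 4th provided submission in the high arm,
  # every 14th in the low arm
  prov_ids <- it$image_id[it$split == "gt_provided"]
  for (rid in unique(ds$exposure$rater_id)) {
    n_prov <- sum(dem$rater_id == rid & dem$image_id %in% prov_ids)
    every <- if (arm_of[rid] == "high_feedback") 4 else 14
    expect_equal(sum(ds$exposure$rater_id == rid), ceiling(n_prov / every))
  }
  # determinism
  ds2 <- simulate_study(cfg, seed = 17)
  expect_identical(demarcations_table(ds), demarcations_table(ds2))
  expect_identical(ds$demarcations[[5]]$mask, ds2$demarcations[[5]]$mask)

  cfg$arms$high_feedback$demarcations_per_image <- 99
  expect_error(simulate_study(cfg, seed = 1), "infeasible")
})
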