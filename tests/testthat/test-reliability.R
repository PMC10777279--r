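test_that("rater tracking averages only over ground-truth-provided images", {
  raters <- data.frame(
    rater_id = c("A", "B"), arm = "low_feedback", stringsAsFactors = FALSE
  )
  gt <- matrix(FALSE, 10, 10); gt[3:6, 3:6] <- TRUE # the fixture default
  off <- matrix(FALSE, 10, 10); off[8:9, 8:9] <- TRUE
  # A matches ground truth on provided images but fails on withheld ones;
  # B half-overlaps everywhere
  bmask <- matrix(FALSE, 10, 10); bmask[3:6, 3:4] <- TRUE
  ds <- tiny_dataset(
    raters, n_images = 4,
    splits = c("gt_provided", "gt_provided", "gt_provided", "gt_withheld"),
    mask_fun = function(rid, iid) {
      if (rid == "A") { if (iid == "I04") off else gt } else bmask
    }
  )
  sc <- track_rater_performance(ds, "mean_dice")
  expect_equal(sc$value[sc$rater_id == "A"], 1) # withheld miss does not count
  expect_equal(sc$value[sc$rater_id == "B"], 2 * 8 / (8 + 16))
  expect_equal(sc$n_scored, c(3L, 3L))

  sae <- track_rater_performance(ds, "mean_sae")
  expect_equal(sae$value[sae$rater_id == "A"], 0)
  expect_equal(sae$value[sae$rater_id == "B"], abs(8 - 16)) # 8 vs 16 of 100 skin px

  expect_error(
    track_rater_performance(
      tiny_dataset(raters, 2, splits = rep("gt_withheld", 2),
                   mask_fun = function(rid, iid) gt)
    ),
    "gt_provided"
  )
})

test_that("unscored raters are flagged and rank last in top-k selection", {
  raters <- data.frame(
    rater_id = paste0("R", 1:3), arm = "low_feedback", stringsAsFactors = FALSE
  )
  gt <- matrix(FALSE, 10, 10); gt[3:6, 3:6] <- TRUE
  skin <- matrix(TRUE, 10, 10)
  images <- list(
    skin_image("I01", "P1", "0_0", skin, gt, "gt_provided"),
    skin_image("I02", "P2", "0_0", skin, gt, "gt_withheld")
  )
  profiles <- lapply(1:3, function(i) {
    rater_profile(paste0("R", i), "low_feedback", i)
  })
  # R3 never marks a provided image, so they have no reliability score
  dem <- list(
    demarc_from_mask(gt, "R1", "I01", 1L, skin = skin),
    demarc_from_mask(gt, "R2", "I01", 2L, skin = skin),
    demarc_from_mask(gt, "R1", "I02", 1L, skin = skin),
    demarc_from_mask(gt, "R2", "I02", 2L, skin = skin),
    demarc_from_mask(gt, "R3", "I02", 3L, skin = skin)
  )
  ds2 <- study_dataset(images, profiles, dem)
  sc <- track_rater_performance(ds2, "mean_dice")
  expect_true(sc$unscored[sc$rater_id == "R3"])
  expect_equal(sc$n_scored[sc$rater_id == "R3"], 0L)

  withheld <- image_demarcations(ds2, "I02")
  top2 <- select_top_k(withheld, sc, 2)
  expect_false("R3" %in% vapply(top2, function(d) d$rater_id, character(1)))
})

test_that("top-k selection follows score order, tie-break, and pool limits", {
  # 7 raters with distinct known scores on one image
  scores <- data.frame(
    rater_id = paste0("R", 1:7), metric_name = "mean_dice",
    value = c(0.9, 0.5, 0.7, 0.95, 0.6, 0.8, 0.4),
    n_scored = 3L, unscored = FALSE, enrollment_order = 1:7,
    stringsAsFactors = FALSE
  )
  ds <- lapply(1:7, function(i) {
    m <- matrix(FALSE, 5, 5); m[i %% 5 + 1, 1] <- TRUE
    demarc_from_mask(m, paste0("R", i), "I", i)
  })
  top5 <- select_top_k(ds, scores, 5)
  got <- vapply(top5, function(d) d$rater_id, character(1))
  # brute-force oracle: sort by score descending
  want <- scores$rater_id[order(-scores$value)][1:5]
  expect_setequal(got, want)
  # output ordered by sequence index
  expect_equal(vapply(top5, function(d) d$sequence_index, integer(1)),
               sort(vapply(top5, function(d) d$sequence_index, integer(1))))

  # k >= pool: everything returned, with a warning
  expect_warning(all7 <- select_top_k(ds, scores, 10), "only 7")
  expect_length(all7, 7)

  # tie broken by smaller enrollment order
  scores$value <- c(0.9, 0.9, 0.5, 0.5, 0.5, 0.5, 0.5)
  scores$enrollment_order <- c(5L, 2L, 3L, 4L, 1L, 6L, 7L)
  top1 <- select_top_k(ds, scores, 1)
  expect_equal(top1[[1]]$rater_id, "R2")

  # lower-is-better metric flips the ordering
  scores$metric_name <- "mean_sae"
  scores$value <- 1:7
  expect_equal(select_top_k(ds, scores, 1)[[1]]$rater_id, "R1")

  expect_error(select_top_k(list(), scores, 2), "at least one")
})

test_that("learning curves bin each rater's own submission stream", {
  raters <- data.frame(rater_id = c("A", "B"), arm = "low_feedback",
                       stringsAsFactors = FALSE)
  gt <- matrix(FALSE, 10, 10); gt[3:6, 3:6] <- TRUE # 16 px = 16% of skin
  # A: constant error (marks nothing -> SAE 16 on every affected image)
  # B: error shrinks with experience (rater_seq = image number in fixture)
  ds <- tiny_dataset(
    raters, n_images = 6, splits = rep("gt_withheld", 6),
    mask_fun = function(rid, iid) {
      if (rid == "A") matrix(FALSE, 10, 10) else gt
    }
  )
  lc <- learning_curve(ds, window = 2L, horizon = 6L)
  a <- lc[lc$rater_id == "A", ]
  expect_equal(nrow(a), 3)
  expect_equal(a$mean_error, rep(16, 3))
  expect_equal(a$bin_start, c(1L, 3L, 5L))
  expect_equal(a$bin_end, c(2L, 4L, 6L))
  b <- lc[lc$rater_id == "B", ]
  expect_equal(b$mean_error, rep(0, 3))

  # a rater short of the horizon is excluded
  lc2 <- learning_curve(ds, window = 2L, horizon = 8L)
  expect_equal(nrow(lc2), 0)

  expect_error(learning_curve(ds, window = 7L, horizon = 6L), "exceed")
  expect_error(learning_curve(ds, window = 4L, horizon = 6L), "divide")
})
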