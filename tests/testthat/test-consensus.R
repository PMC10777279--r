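test_that("vote counts tally per-pixel markings", {
  m1 <- matrix(FALSE, 6, 6); m1[1:3, 1:3] <- TRUE
  m2 <- matrix(FALSE, 6, 6); m2[2:4, 2:4] <- TRUE
  d1 <- demarc_from_mask(m1, "A", "I", 1)
  d2 <- demarc_from_mask(m2, "B", "I", 2)

  vc <- vote_counts(list(d1))
  expect_identical(vc$counts, m1 + 0L)

  vc3 <- vote_counts(list(d1, demarc_from_mask(m1, "B", "I", 2),
                          demarc_from_mask(m1, "C", "I", 3)))
  expect_true(all(vc3$counts %in% c(0L, 3L)))

  # total votes equal the summed individual areas (brute-force tally)
  set.seed(5)
  ds <- lapply(1:5, function(i) demarc_from_mask(random_mask(6, 6), paste0("R", i), "I", i))
  vc <- vote_counts(ds)
  expect_equal(sum(vc$counts), sum(vapply(ds, function(d) mask_area(d$mask), numeric(1))))

  expect_error(vote_counts(list()), "at least one")
  expect_error(vote_counts(list(d1, demarc_from_mask(m1, "B", "J", 1))), "mix image_ids")
  expect_error(
    vote_counts(list(d1, demarc_from_mask(matrix(TRUE, 3, 3), "B", "I", 2))),
    "shapes differ"
  )
})

test_that("plurality vote includes pixels at exactly half of an even crowd", {
  base <- matrix(FALSE, 4, 4)
  half <- base; half[1, 1] <- TRUE
  ds <- list(
    demarc_from_mask(half, "A", "I", 1),
    demarc_from_mask(half, "B", "I", 2),
    demarc_from_mask(base, "C", "I", 3),
    demarc_from_mask(base, "D", "I", 4)
  )
  cm <- majority_vote(ds) # 2 of 4 votes = 50% -> included
  expect_true(cm$mask[1, 1])

  # one rater is their own majority
  solo <- majority_vote(list(demarc_from_mask(half, "A", "I", 1)))
  expect_identical(solo$mask, half)

  # three disjoint markings: each pixel at 1/3 < 50%
  m <- lapply(1:3, function(i) {
    x <- matrix(FALSE, 4, 4); x[i, i] <- TRUE; x
  })
  dis <- majority_vote(lapply(1:3, function(i) demarc_from_mask(m[[i]], LETTERS[i], "I", i)))
  expect_equal(mask_area(dis$mask), 0)
})

test_that("majority vote matches the per-pixel oracle and its invariants", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(2:7, 1)
    masks <- lapply(seq_len(n), function(i) random_mask(8, 8, runif(1, 0.2, 0.6)))
    ds <- lapply(seq_len(n), function(i) demarc_from_mask(masks[[i]], paste0("R", i), "I", i))
    cm <- majority_vote(ds)
    expect_identical(cm$mask, oracle_majority(masks))
    # permutation invariance
    perm <- sample(n)
    expect_identical(majority_vote(ds[perm])$mask, cm$mask)
  }
  # unanimity
  m <- random_mask(8, 8)
  ds <- lapply(1:4, function(i) demarc_from_mask(m, paste0("R", i), "I", i))
  expect_identical(majority_vote(ds)$mask, m)
  # adding a superset of the consensus never removes consensus pixels
  set.seed(31)
  for (rep in 1:10) {
    masks <- lapply(1:3, function(i) random_mask(8, 8, 0.4))
    ds <- lapply(1:3, function(i) demarc_from_mask(masks[[i]], paste0("R", i), "I", i))
    cm <- majority_vote(ds)
    sup <- cm$mask | random_mask(8, 8, 0.2)
    cm2 <- majority_vote(c(ds, list(demarc_from_mask(sup, "S", "I", 4))))
    expect_true(mask_subset(cm$mask, cm2$mask))
  }
})

test_that("crowd assembly takes the earliest arm demarcations", {
  raters <- data.frame(
    rater_id = c(paste0("H", 1:2), paste0("L", 1:5)),
    arm = c(rep("high_feedback", 2), rep("low_feedback", 5)),
    stringsAsFactors = FALSE
  )
  # every rater marks every image with their own corner pixel
  masks <- list()
  mask_fun <- function(rid, iid) {
    m <- matrix(FALSE, 10, 10)
    m[match(rid, raters$rater_id), 1] <- TRUE
    m
  }
  ds <- tiny_dataset(raters, n_images = 2, mask_fun = mask_fun)

  cw <- crowd_spec("low3", "low_feedback", first_r = 3)
  picked <- assemble_crowd(ds, "I01", cw)
  expect_length(picked, 3)
  # lowest sequence indices within the arm, in order
  expect_equal(vapply(picked, function(d) d$sequence_index, integer(1)), 3:5)
  expect_true(all(vapply(picked, function(d) d$rater_id, character(1)) %in% paste0("L", 1:5)))

  one <- assemble_crowd(ds, "I01", crowd_spec("low1", "low_feedback", first_r = 1))
  expect_equal(one[[1]]$sequence_index, 3L)

  expect_error(
    assemble_crowd(ds, "I01", crowd_spec("high9", "high_feedback", first_r = 9)),
    "I01"
  )
  expect_error(crowd_spec("x", "low_feedback"), "exactly one")
  expect_error(crowd_spec("x", "low_feedback", first_r = 2, top_k = 2), "exactly one")
})
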