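test_that("crowd summaries use interpolated quartiles and are permutation-invariant", {
  sc <- data.frame(
    label = "c", image_id = paste0("I", 1:5),
    dice = c(0.1, 0.2, 0.3, 0.4, 0.5),
    surface_area_error = c(1, 2, 3, 4, 5),
    stringsAsFactors = FALSE
  )
  s <- summarize_crowd(sc, "c")
  expect_equal(s$median_sae, 3)
  expect_equal(c(s$iqr_sae_lo, s$iqr_sae_hi), c(2, 4))
  expect_equal(s$mean_sae, 3)
  expect_equal(s$n_images, 5)

  perm <- summarize_crowd(sc[sample(5), ], "c")
  expect_equal(perm, s)

  one <- summarize_crowd(sc[2, ], "c")
  expect_equal(one$median_dice, 0.2)
  expect_equal(one$mean_dice, 0.2)
  expect_equal(one$iqr_dice_lo, one$iqr_dice_hi)

  # hand-computed 6-row fixture
  sc6 <- data.frame(
    label = "c", image_id = paste0("I", 1:6),
    dice = c(0.62, 0.80, 0.71, 0.90, 0.55, 0.77),
    surface_area_error = c(12, 4, 8, 2, 20, 6),
    stringsAsFactors = FALSE
  )
  s6 <- summarize_crowd(sc6, "c")
  expect_equal(s6$median_dice, (0.71 + 0.77) / 2)
  expect_equal(s6$median_sae, 7)
  expect_equal(s6$mean_sae, 52 / 6)
  expect_equal(s6$iqr_sae_lo, 4.5)  # type-7 interpolation
  expect_equal(s6$iqr_sae_hi, 11)
  expect_gte(s6$median_sae, s6$iqr_sae_lo)
  expect_lte(s6$median_sae, s6$iqr_sae_hi)

  expect_error(summarize_crowd(sc, "missing"), "no score rows")
})

test_that("Mann-Whitney comparison: exact small-sample behaviour", {
  r <- compare_crowds(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1) # 2/20 labelings are as extreme
  expect_equal(r$method, "exact")

  # identical samples: complete tie symmetry
  x <- c(2, 2, 3, 3)
  r2 <- compare_crowds(x, x)
  expect_equal(r2$U, length(x)^2 / 2)
  expect_equal(r2$p_value, 1)

  # swapping samples reflects U and keeps p
  a <- c(1.2, 3.4, 2.2, 5.0)
  b <- c(0.5, 2.8, 4.1)
  r_ab <- compare_crowds(a, b)
  r_ba <- compare_crowds(b, a)
  expect_equal(r_ba$U, length(a) * length(b) - r_ab$U)
  expect_equal(r_ba$p_value, r_ab$p_value)

  expect_error(compare_crowds(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney normal approximation agrees with the classical test", {
  set.seed(3)
  a <- rnorm(20, 1)
  b <- rnorm(25, 1.4)
  r <- compare_crowds(a, b)
  expect_equal(r$method, "normal")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(r$U, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
  # tie correction matches too
  at <- round(a * 2) / 2
  bt <- round(b * 2) / 2
  rt <- compare_crowds(at, bt)
  reft <- stats::wilcox.test(at, bt, exact = FALSE, correct = FALSE)
  expect_equal(rt$p_value, reft$p.value, tolerance = 1e-10)
})

test_that("photo spread orders photos by descending median error", {
  image_map <- data.frame(
    image_id = paste0("I", 1:6),
    photo_id = rep(c("PA", "PB", "PC"), each = 2),
    view_label = rep(c("0_0", "+15_0"), 3),
    stringsAsFactors = FALSE
  )
  sc <- data.frame(
    image_id = paste0("I", 1:6),
    surface_area_error = c(5, 5, 12, 14, 3, 1),
    stringsAsFactors = FALSE
  )
  sp <- photo_spread(sc, image_map)
  expect_equal(sp$table$photo_id, c("PB", "PA", "PC"))
  expect_equal(sp$table$median_error, c(13, 5, 2))
  expect_equal(sp$table$min_error, c(12, 5, 1))
  expect_equal(sp$table$max_error, c(14, 5, 3))
  expect_equal(sp$table$n_views, rep(2L, 3))
  # identical views -> zero-width range
  expect_equal(sp$table$max_error[2] - sp$table$min_error[2], 0)
  expect_error(photo_spread(data.frame(image_id = "zz", surface_area_error = 1),
                            image_map), "missing")
})

test_that("variability-vs-error regression recovers exact linear structure", {
  image_map <- data.frame(
    image_id = paste0("I", 1:4), photo_id = paste0("P", 1:4),
    view_label = "0_0", stringsAsFactors = FALSE
  )
  # rater fractions chosen so per-photo SDs are 1, 2, 3, 4
  fr <- do.call(rbind, lapply(1:4, function(k) {
    data.frame(
      image_id = paste0("I", k), rater_id = c("A", "B"),
      fraction = c(10 - k / sqrt(2), 10 + k / sqrt(2)),
      stringsAsFactors = FALSE
    )
  }))
  cs <- data.frame(
    image_id = paste0("I", 1:4),
    surface_area_error = 2 * (1:4) + 1, # exactly on y = 2x + 1
    stringsAsFactors = FALSE
  )
  ve <- variability_vs_error(cs, fr, image_map)
  expect_equal(ve$slope, 2, tolerance = 1e-10)
  expect_equal(ve$intercept, 1, tolerance = 1e-10)
  expect_equal(ve$r_squared, 1, tolerance = 1e-10)
  expect_equal(ve$n_points, 4)

  # constant response: slope 0, no explainable variance
  cs0 <- cs
  cs0$surface_area_error <- 7
  ve0 <- variability_vs_error(cs0, fr, image_map)
  expect_equal(ve0$slope, 0, tolerance = 1e-10)
  expect_equal(ve0$r_squared, 0)

  # closed-form normal-equations oracle on 4 points
  x <- ve$points$sd_fraction
  y <- c(3.2, 4.8, 9.1, 7.7)
  cs2 <- cs
  cs2$surface_area_error <- y
  ve2 <- variability_vs_error(cs2, fr, image_map)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  r2 <- (sum((x - mean(x)) * (y - mean(y))))^2 /
    (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ve2$slope, beta, tolerance = 1e-10)
  expect_equal(ve2$intercept, alpha, tolerance = 1e-10)
  expect_equal(ve2$r_squared, r2, tolerance = 1e-10)

  expect_error(
    variability_vs_error(cs[1:2, ], fr[fr$image_id %in% c("I1", "I2"), ], image_map),
    "at least 3"
  )
})
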