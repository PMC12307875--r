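test_that("contrast stretch maps percentile bounds onto [0, 1]", {
  const <- matrix(5, 10, 10)
  expect_true(all(preprocess_channel(const) == 0))

  two <- matrix(c(0, 100), 8, 8)
  out <- preprocess_channel(two, stretch = c(0, 100))
  expect_setequal(unique(as.numeric(out)), c(0, 1))

  withr::with_seed(1, {
    x <- matrix(runif(400, 10, 50), 20, 20)
    out <- preprocess_channel(x, stretch = c(0, 100))
    expect_equal(min(out), 0)
    expect_equal(max(out), 1)
    # interior percentiles clip the tails
    out2 <- preprocess_channel(x, stretch = c(5, 95))
    expect_gt(mean(out2 == 0), 0)
    expect_gt(mean(out2 == 1), 0)
  })
  expect_error(preprocess_channel(two, stretch = c(50, 20)), "stretch")
  expect_error(preprocess_channel(matrix(numeric(0), 0, 0)), "matrix")
})

test_that("batch preprocessing enforces one parameter set per comparison", {
  imgs <- lapply(1:3, function(i)
    sim_cell_image(sample_id = paste0("s", i), seed = i)$image)
  out <- preprocess_batch(imgs, "er", stretch = c(0, 100))
  expect_length(out, 3)
  expect_named(out, c("s1", "s2", "s3"))
  expect_error(
    preprocess_batch(imgs, "er", stretch = list(c(0, 100), c(1, 99))),
    "uniformly")
  expect_error(preprocess_batch(imgs, "nope"), "missing")
})

test_that("small-object filter removes components under 10 px, keeps 10 px", {
  # three 8-connected components of areas 5, 10 and 23 in one channel
  ch <- matrix(0, 30, 30)
  ch[2, 2:6] <- 1               # area 5
  ch[10:11, 10:14] <- 1         # area 10
  ch[20:22, 20:26] <- 1; ch[23, 20:21] <- 1  # area 23
  lm <- binarize_and_filter(ch, 0.5, min_size = 10)
  expect_equal(lm$n_objects, 2)
  expect_setequal(tabulate(lm$labels)[tabulate(lm$labels) > 0], c(10, 23))

  blank <- binarize_and_filter(matrix(0, 16, 16), 0.5)
  expect_equal(blank$n_objects, 0)
  expect_equal(sum(blank$mask), 0)
  expect_error(binarize_and_filter(ch, 1.5), "threshold")
})

test_that("surviving components equal a flood-fill census oracle", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      m <- random_mask(48, 48, p = 0.22)
      lm <- binarize_and_filter(m * 1, 0.5, min_size = 10)
      oracle_labels <- flood_fill_label(m, connectivity = 8)
      sizes <- tabulate(oracle_labels)
      surviving <- oracle_labels %in% which(sizes >= 10) &
        oracle_labels > 0
      expect_identical(lm$mask, matrix(surviving, 48, 48))
    }
  })
})

test_that("8-connected labeling matches the flood-fill oracle", {
  withr::with_seed(4, {
    for (rep in 1:10) {
      m <- random_mask(40, 40, p = 0.35)
      expect_identical(label_components(m, 8), flood_fill_label(m, 8))
      expect_identical(label_components(m, 4), flood_fill_label(m, 4))
    }
  })
})

test_that("overlap_pixels counts shared coordinates", {
  m <- random_mask(32, 32, p = 0.4)
  same <- overlap_pixels(m, m)
  expect_equal(same$overlap_pixels, same$pixels_a)
  expect_equal(same$pixels_a, sum(m))

  a <- matrix(FALSE, 10, 10); a[1:5, ] <- TRUE
  b <- matrix(FALSE, 10, 10); b[6:10, ] <- TRUE
  expect_equal(overlap_pixels(a, b)$overlap_pixels, 0)

  withr::with_seed(2, {
    for (rep in 1:25) {
      a <- random_mask(64, 64); b <- random_mask(64, 64)
      expect_equal(overlap_pixels(a, b)$overlap_pixels,
                   brute_overlap_count(a, b))
    }
  })
  expect_error(overlap_pixels(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               "shape")
})

test_that("overlap never decreases when a mask is dilated", {
  withr::with_seed(6, {
    for (rep in 1:10) {
      a <- random_mask(48, 48, 0.15); b <- random_mask(48, 48, 0.15)
      base <- overlap_pixels(a, b)$overlap_pixels
      expect_gte(overlap_pixels(dilate_mask(a, 1), b)$overlap_pixels, base)
      expect_gte(overlap_pixels(a, dilate_mask(b, 2))$overlap_pixels, base)
    }
  })
})

test_that("overlap index normalizes to the control-group mean", {
  meas <- data.frame(sample_id = c("c1", "c2", "s1"),
                     group = c("control", "control", "stress"),
                     overlap_pixels = c(10, 20, 30))
  oi <- overlap_index(meas, "control")
  expect_equal(oi$per_sample$overlap_index, c(10, 20, 30) / 15)
  expect_equal(oi$summary$mean_index[oi$summary$group == "stress"], 2.0)
  expect_equal(oi$summary$mean_index[oi$summary$group == "control"], 1.0)

  same <- data.frame(sample_id = c("a", "b"), group = "control",
                     overlap_pixels = c(7, 7))
  expect_true(all(overlap_index(same, "control")$per_sample$overlap_index
                  == 1))

  single <- data.frame(sample_id = "a", group = "control",
                       overlap_pixels = 5)
  oi1 <- overlap_index(single, "control")
  expect_equal(oi1$per_sample$overlap_index, 1.0)
  expect_true(is.na(oi1$summary$sem_index))

  zero <- data.frame(sample_id = "a", group = "control",
                     overlap_pixels = 0)
  expect_error(overlap_index(zero, "control"), "undefined")
  expect_error(overlap_index(meas, "missing_group"), "empty")
})

test_that("triple overlap reduces to pairwise and matches a loop oracle", {
  a <- random_mask(32, 32); b <- random_mask(32, 32)
  all_on <- matrix(TRUE, 32, 32)
  expect_equal(triple_overlap(a, b, all_on)$overlap_pixels,
               overlap_pixels(a, b)$overlap_pixels)
  none <- matrix(FALSE, 32, 32)
  expect_equal(triple_overlap(a, b, none)$overlap_pixels, 0)
  withr::with_seed(3, {
    for (rep in 1:10) {
      x <- random_mask(24, 24); y <- random_mask(24, 24)
      z <- random_mask(24, 24)
      n <- 0L
      for (i in 1:24) for (j in 1:24)
        if (x[i, j] && y[i, j] && z[i, j]) n <- n + 1L
      expect_equal(triple_overlap(x, y, z)$overlap_pixels, n)
    }
  })
})

test_that("Pearson colocalization agrees with the covariance formula", {
  withr::with_seed(5, {
    x <- matrix(runif(900), 30, 30)
    expect_equal(pearson_colocalization(x, x), 1.0, tolerance = 1e-10)
    expect_equal(pearson_colocalization(x, max(x) - x), -1.0,
                 tolerance = 1e-10)
    for (rep in 1:10) {
      a <- matrix(runif(400), 20, 20); b <- matrix(runif(400), 20, 20)
      expect_equal(pearson_colocalization(a, b), pearson_oracle(a, b),
                   tolerance = 1e-10)
    }
    roi <- random_mask(20, 20, 0.5)
    a <- matrix(runif(400), 20, 20); b <- matrix(runif(400), 20, 20)
    expect_equal(pearson_colocalization(a, b, roi),
                 pearson_oracle(a[roi], b[roi]), tolerance = 1e-10)
  })
  flat <- matrix(1, 10, 10)
  noisy <- matrix(runif(100), 10, 10)
  expect_warning(r <- pearson_colocalization(flat, noisy), "zero variance")
  expect_true(is.na(r))
})
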