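test_that("length categories follow the 2.5/5 um bins with closed middle", {
  expect_equal(as.character(classify_length(2.0)), "fragmented")
  expect_equal(as.character(classify_length(2.5)), "intermediate")
  expect_equal(as.character(classify_length(5.0)), "intermediate")
  expect_equal(as.character(classify_length(6.0)), "filamentous")
  expect_equal(as.character(classify_length(0)), "fragmented")
  expect_error(classify_length(-1), ">= 0")

  # the binning is total and exclusive over random non-negative lengths
  withr::with_seed(1, {
    lens <- runif(500, 0, 12)
    cats <- classify_length(lens)
    expect_false(any(is.na(cats)))
    expect_true(all((lens < 2.5) == (cats == "fragmented")))
    expect_true(all((lens > 5) == (cats == "filamentous")))
  })
})

test_that("a straight 20-px capsule measures 2.0 um at 0.1 um/px", {
  r <- sim_capsule_image(n_capsules = 1, length_um = 2, width_px = 5,
                         pixel_size = 0.1, noise_sd = 0, seed = 3)
  obj <- measure_lengths(binarize_and_filter(r$image$channels$mito, 0.3),
                         pixel_size = 0.1)
  expect_equal(nrow(obj), 1)
  expect_equal(obj$length_um, 2.0, tolerance = 0.1)
})

test_that("objects below the minimum size are excluded", {
  m <- matrix(FALSE, 20, 20)
  m[5, 5] <- TRUE                     # isolated pixel
  m[10:12, 4:9] <- TRUE               # 18-px object
  obj <- measure_lengths(m, pixel_size = 0.1, min_size = 10)
  expect_equal(nrow(obj), 1)
  expect_equal(obj$area_px, 18)
  expect_equal(nrow(measure_lengths(matrix(FALSE, 8, 8), 0.1)), 0)
  expect_error(measure_lengths(m, pixel_size = 0), "pixel_size")
})

test_that("lengths recover capsule ground truth within 10%", {
  r <- sim_capsule_image(n_capsules = 30, width = 320, height = 320,
                         noise_sd = 0, seed = 11)
  obj <- measure_lengths(binarize_and_filter(r$image$channels$mito, 0.3),
                         pixel_size = 0.07)
  expect_equal(nrow(obj), 30)
  est <- sort(obj$length_um)
  tru <- sort(r$truth$length_um)
  expect_true(all(abs(est - tru) / tru <= 0.10))
})

test_that("doubling the pixel size doubles every length", {
  r <- sim_capsule_image(n_capsules = 8, seed = 13)
  lm <- binarize_and_filter(r$image$channels$mito, 0.3)
  l1 <- measure_lengths(lm, pixel_size = 0.07)
  l2 <- measure_lengths(lm, pixel_size = 0.14)
  expect_equal(l2$length_um, 2 * l1$length_um)
})

test_that("morphology summary pools categories and quartiles per group", {
  objs <- data.frame(length_um = c(1, 3, 7), group = "a")
  s <- summarize_morphology(objs)$summary
  expect_equal(c(s$frac_fragmented, s$frac_intermediate,
                 s$frac_filamentous), rep(1 / 3, 3))
  expect_equal(s$n, 3)
  expect_equal(s$median_um, 3)

  empty <- summarize_morphology(
    data.frame(length_um = numeric(0), group = character(0)))$summary
  expect_null(empty)  # no groups, nothing to summarize

  # known multinomial bin proportions are recovered within 0.05
  withr::with_seed(17, {
    n <- 500
    cat_draw <- sample(c("f", "i", "l"), n, replace = TRUE,
                       prob = c(0.6, 0.3, 0.1))
    lens <- ifelse(cat_draw == "f", runif(n, 0.2, 2.4),
                   ifelse(cat_draw == "i", runif(n, 2.6, 4.9),
                          runif(n, 5.1, 9)))
    s2 <- summarize_morphology(
      data.frame(length_um = lens, group = "g"))$summary
    expect_lt(abs(s2$frac_fragmented - 0.6), 0.05)
    expect_lt(abs(s2$frac_intermediate - 0.3), 0.05)
    expect_lt(abs(s2$frac_filamentous - 0.1), 0.05)
    expect_equal(s2$frac_fragmented + s2$frac_intermediate +
                   s2$frac_filamentous, 1)
  })
})

test_that("category calls match ground truth away from bin boundaries", {
  r <- sim_capsule_image(n_capsules = 30, width = 320, height = 320,
                         noise_sd = 0, seed = 23)
  obj <- measure_lengths(binarize_and_filter(r$image$channels$mito, 0.3),
                         pixel_size = 0.07)
  est <- sort(obj$length_um); tru <- sort(r$truth$length_um)
  away <- abs(tru - 2.5) >= 0.3 & abs(tru - 5) >= 0.3
  expect_identical(classify_length(est[away]), classify_length(tru[away]))
})
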