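test_that("generators are pure functions of parameters and seed", {
  a <- sim_cell_image(seed = 42)
  b <- sim_cell_image(seed = 42)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$contact_mask, b$truth$contact_mask)
  expect_false(identical(a$image$channels,
                         sim_cell_image(seed = 43)$image$channels))

  expect_identical(sim_capsule_image(seed = 7)$truth,
                   sim_capsule_image(seed = 7)$truth)
  expect_identical(sim_reporter_image(12, 0.25, seed = 5),
                   sim_reporter_image(12, 0.25, seed = 5))
  expect_identical(sim_gene_table(seed = 3), sim_gene_table(seed = 3))
  expect_identical(sim_flow_events(50, seed = 2),
                   sim_flow_events(50, seed = 2))
  # generators leave the global RNG state alone
  set.seed(99); before <- .Random.seed
  invisible(sim_atp_plate(0.4, 0.6, seed = 1))
  expect_identical(before, .Random.seed)
})

test_that("empty cell image is blank and degenerate cases validate", {
  r <- sim_cell_image(n_tubules = 0, n_capsules = 0,
                      n_contact_capsules = 0, n_puncta = 0, bg = 0,
                      seed = 1)
  expect_true(all(vapply(r$image$channels, function(ch) all(ch == 0),
                         logical(1))))
  expect_equal(sum(r$truth$er_mask), 0)
  expect_equal(sum(r$truth$contact_mask), 0)
  expect_error(sim_cell_image(width = 32, seed = 1), "64x64")
  expect_error(sim_cell_image(noise_sd = -1, seed = 1), "noise_sd")
  expect_error(sim_cell_image(n_puncta = -2, seed = 1), ">= 0")
})

test_that("cell-image ground truth satisfies the contact invariants", {
  for (s in 1:5) {
    r <- sim_cell_image(noise_sd = 0.05, seed = s)
    d <- r$truth$contact_dilate
    expected <- dilate_mask(r$truth$er_mask, d) &
      dilate_mask(r$truth$mito_mask, d)
    expect_identical(r$truth$contact_mask, expected)
    at <- r$truth$puncta[r$truth$puncta$at_contact, ]
    if (nrow(at) > 0)
      expect_true(all(r$truth$contact_mask[cbind(at$row, at$col)]))
  }
})

test_that("a capsule inside an ER tubule gives contact = capsule exactly", {
  # with dilation 0 and the mitochondrion fully contained in the ER,
  # intersection is the mitochondrial mask itself
  r <- sim_cell_image(n_tubules = 1, tubule_steps = 400, tubule_radius = 12,
                      n_capsules = 0, n_contact_capsules = 1,
                      capsule_length_um = c(0.5, 0.7), capsule_width = 3,
                      contact_dilate = 0, n_puncta = 0, seed = 8)
  if (all(r$truth$mito_mask <= r$truth$er_mask)) {
    expect_identical(r$truth$contact_mask, r$truth$mito_mask)
  }
  expect_identical(r$truth$contact_mask,
                   r$truth$er_mask & r$truth$mito_mask)
})

test_that("capsule image records true lengths and rejects impossible packs", {
  r <- sim_capsule_image(n_capsules = 1, length_um = 2, width_px = 5,
                         pixel_size = 0.1, seed = 1)
  expect_equal(r$truth$length_um, 2.0, tolerance = 1e-12)
  d <- sqrt((r$truth$r2 - r$truth$r1)^2 + (r$truth$c2 - r$truth$c1)^2)
  expect_equal(d * 0.1, r$truth$length_um)

  blank <- sim_capsule_image(n_capsules = 0, seed = 1)
  expect_true(all(blank$image$channels$mito == 0.02))

  expect_error(
    sim_capsule_image(width = 64, height = 64, n_capsules = 60,
                      length_um = 4, max_attempts = 5, seed = 1),
    "place")
  expect_error(sim_capsule_image(width_px = 2, seed = 1), "width_px")
  expect_error(sim_capsule_image(length_um = -1, seed = 1), "> 0")
})

test_that("rendered capsules do not touch each other", {
  r <- sim_capsule_image(n_capsules = 10, seed = 21)
  labs <- label_components(r$image$channels$mito > 0.3)
  expect_equal(max(labs), 10)
})

test_that("reporter puncta counts follow the half-away rounding rule", {
  r <- sim_reporter_image(10, 0.3, seed = 2)
  expect_equal(sum(r$truth$class == "red_only"), 3)
  # 7 * 0.5 = 3.5 rounds away from zero to 4
  r2 <- sim_reporter_image(7, 0.5, seed = 2)
  expect_equal(sum(r2$truth$class == "red_only"), 4)
  r3 <- sim_reporter_image(10, 0, seed = 2)
  expect_true(all(r3$truth$class == "dual"))
  r4 <- sim_reporter_image(10, 1, seed = 2)
  expect_true(all(r4$image$channels$green == 0.05))
  expect_error(sim_reporter_image(10, 1.2, seed = 1), "red_only_fraction")
})

test_that("calcium generator matches its closed forms", {
  flat <- sim_calcium_traces(rate = 0, noise_sd = 0, seed = 1)
  expect_true(all(flat$indicator == flat$indicator[1]))

  # shared bleaching factor leaves the indicator/reference ratio constant
  bl <- sim_calcium_traces(rate = 0, bleach_rate = 0.002, noise_sd = 0,
                           seed = 1)
  expect_equal(bl$indicator / bl$reference,
               rep((bl$indicator / bl$reference)[1], nrow(bl)))

  ef <- sim_calcium_traces("efflux", rate = 0.01, amplitude = 100,
                           n_timepoints = 101, dt = 1, noise_sd = 0,
                           seed = 1)
  i100 <- ef$indicator[ef$time == 100]
  expect_equal(i100 / ef$indicator[1], exp(-1), tolerance = 1e-12)

  expect_error(sim_calcium_traces(rate = -0.1, seed = 1), "rate")
  expect_error(sim_calcium_traces(n_timepoints = 1, seed = 1),
               "n_timepoints")
})

test_that("ATP plate condition means follow the generative rule", {
  p <- sim_atp_plate(0, 0, baseline = 1000, cv = 0, seed = 1)$plate
  expect_true(all(p$rlu == 1000))

  p2 <- sim_atp_plate(0.6, 0.75, baseline = 1000, cv = 0, seed = 1)$plate
  means <- tapply(p2$rlu, p2$condition, mean)
  expect_equal(unname(means["DG"]), 400)
  expect_equal(unname(means["OA"]), 250)
  expect_equal(unname(means["DGOA"]), 1000 * 0.4 * 0.25)
  # cv = 0: replicates identical within condition
  expect_true(all(tapply(p2$rlu, p2$condition, function(v)
    length(unique(v)) == 1)))
  expect_error(sim_atp_plate(0.5, 0.5, cv = -1, seed = 1), "cv")
  expect_error(sim_atp_plate(1.5, 0.5, seed = 1), "fractions")
})

test_that("gene table spikes respect effect and significance bounds", {
  g <- sim_gene_table(n_null = 1000, n_up = 25, n_down = 15, seed = 9)
  expect_equal(nrow(g$table), 1040)
  expect_equal(sum(g$table$truth == "up"), 25)
  up <- g$table[g$table$truth == "up", ]
  down <- g$table[g$table$truth == "down", ]
  expect_true(all(up$log2fc >= 2) && all(up$pvalue <= 0.01))
  expect_true(all(down$log2fc <= -2) && all(down$pvalue <= 0.01))
  expect_equal(length(g$mito_genes), 100)

  g0 <- sim_gene_table(n_up = 0, n_down = 0, n_mito_genes = 50, seed = 9)
  expect_true(all(g0$table$truth == "null"))
  expect_error(sim_gene_table(n_null = 10, n_up = 0, n_down = 0,
                              n_mito_genes = 50, seed = 1), "exceeds")
})

test_that("flow events follow the lognormal model", {
  ev <- sim_flow_events(5, log_mean = c(TMRM = 7, MTG = 6), log_sd = 0,
                        seed = 1)
  expect_equal(nrow(ev), 5)
  expect_true(all(ev$TMRM == exp(7)))
  expect_true(all(ev$MTG == exp(6)))
  expect_error(sim_flow_events(0, seed = 1), "n_events")
  expect_error(sim_flow_events(5, log_sd = -1, seed = 1), "log_sd")
})

test_that("noiseless renders reproduce the stored masks pixel for pixel", {
  r <- sim_cell_image(noise_sd = 0, seed = 31)
  expect_identical(r$image$channels$er > 0.3, r$truth$er_mask)
  expect_identical(r$image$channels$mito > 0.3, r$truth$mito_mask)
  rc <- sim_capsule_image(noise_sd = 0, seed = 31)
  expect_equal(sum(rc$image$channels$mito > 0.3) > 0, TRUE)
})
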