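test_that("identical seeds reproduce frames and ground truth bit-identically", {
  cfg <- small_config(nonspecific_dab_per_fov = 20)
  a <- simulate_fov(cfg, 300, rng_seed = 42)
  b <- simulate_fov(cfg, 300, rng_seed = 42)
  expect_identical(a$frame$pixels, b$frame$pixels)
  expect_identical(a$truth, b$truth)
  t1 <- simulate_titration(cfg, c(0, 100), fovs_per_concentration = 2, rng_seed = 7)
  t2 <- simulate_titration(cfg, c(0, 100), fovs_per_concentration = 2, rng_seed = 7)
  expect_identical(lapply(t1, `[[`, "truth"), lapply(t2, `[[`, "truth"))
})

test_that("no analyte and no background leaves the detection channel empty", {
  cfg <- small_config(nonspecific_dab_per_fov = 0)
  sim <- simulate_fov(cfg, 0, rng_seed = 1)
  expect_identical(nrow(sim$truth$dab_specific), 0L)
  expect_identical(nrow(sim$truth$dab_nonspecific), 0L)
  # right half is camera noise around the background level only
  right <- sim$frame$pixels[, 129:256]
  expect_lt(abs(mean(right) - cfg$background_level), 1)
})

test_that("occupancy follows the Langmuir isotherm at half-saturation", {
  # ~10,000 capture antibodies across FOVs at c = kd with bmax_fraction 1
  cfg <- small_config(cab_count_range = c(500L, 500L), bmax_fraction = 1,
                      min_separation_px = 0)
  bound <- 0L; total <- 0L
  for (i in 1:20) {
    tr <- simulate_fov(cfg, cfg$kd, rng_seed = 100 + i)$truth
    bound <- bound + sum(tr$cab$bound); total <- total + nrow(tr$cab)
  }
  se <- sqrt(0.25 / total)
  expect_lt(abs(bound / total - 0.5), 3 * se)
})

test_that("ground-truth bound fraction rises monotonically along the ladder", {
  cfg <- small_config(cab_count_range = c(300L, 300L), min_separation_px = 0)
  ladder <- c(10, 100, 300, 1000, 20000)
  frac <- sapply(seq_along(ladder), function(i) {
    tr <- simulate_fov(cfg, ladder[i], rng_seed = 500 + i)$truth
    mean(tr$cab$bound)
  })
  expect_true(all(diff(frac) > 0))
})

test_that("dye labeling is Poisson with the documented zero-dye tail", {
  expect_identical(sample_dye_counts(0, 50, rng_seed = 1), rep(0L, 50))
  # exact pmf at x = 0 for DOL 3
  expect_equal(exp(-3), dpois(0, 3))
  n <- 1e5
  x <- sample_dye_counts(3, n, rng_seed = 9)
  expect_lt(abs(mean(x) - 3), 3 * sqrt(3 / n))
  # goodness of fit against the Poisson pmf, not rejected at alpha = 0.01
  tab <- table(factor(pmin(x, 9), levels = 0:9))
  p <- c(dpois(0:8, 3), 1 - ppois(8, 3))
  expect_gt(chisq.test(as.vector(tab), p = p)$p.value, 0.01)
  # zero-dye antibodies are rare at DOL >= 3
  expect_lt(mean(x == 0), exp(-3) + 3 * sqrt(exp(-3) / n))
  expect_error(sample_dye_counts(-1, 10), "dol")
})

test_that("ground-truth dAb bookkeeping is conserved and paired", {
  cfg <- small_config(nonspecific_dab_per_fov = 15)
  sim <- simulate_fov(cfg, 1000, rng_seed = 3)
  tr <- sim$truth
  expect_identical(nrow(tr$dab_specific), sum(tr$cab$bound))
  expect_true(all(tr$dab_specific$pair_id %in% which(tr$cab$bound)))
  # specific dAbs map back near their capture antibody under the true map
  mapped <- apply_transform(cfg$true_transform,
                            as.matrix(tr$dab_specific[, c("x", "y")]))
  d <- sqrt((mapped[, 1] - tr$cab$x[tr$dab_specific$pair_id])^2 +
            (mapped[, 2] - tr$cab$y[tr$dab_specific$pair_id])^2)
  expect_true(all(d < 4 * cfg$jitter_sd_px + 1e-9))
})

test_that("bead frames pair channels through the true transform", {
  tt <- affine2d(rbind(c(1, 0, 2.5), c(0, 1, -1.5), c(0, 0, 1)))
  bf <- simulate_bead_frames(tt, n_frames = 2, beads_per_frame = 10,
                             jitter_sd_px = 0, rng_seed = 4,
                             image_height_px = 128L, image_width_px = 128L)
  expect_length(bf, 2L)
  for (b in bf) {
    back <- apply_transform(tt, b$detection_xy)
    expect_equal(unname(back), unname(as.matrix(b$capture_xy)), tolerance = 1e-12)
  }
  # identity transform, zero jitter: both channels see identical coordinates
  bi <- simulate_bead_frames(affine_identity(), 1, 5, 0, rng_seed = 5,
                             image_height_px = 128L, image_width_px = 128L)
  expect_equal(unname(as.matrix(bi[[1]]$capture_xy)),
               unname(bi[[1]]$detection_xy), tolerance = 1e-12)
  expect_error(simulate_bead_frames(tt, 1, 2), "beads_per_frame")
})

test_that("generator rejects invalid inputs", {
  cfg <- small_config()
  expect_error(simulate_fov(cfg, -5), "concentration")
  expect_error(simulate_titration(cfg, numeric(0)), "non-empty")
  expect_error(sim_config(kd = -1), "kd")
  expect_error(sim_config(bmax_fraction = 1.5), "bmax_fraction")
  expect_error(sim_config(cab_count_range = c(50, 10)), "cab_count_range")
})

test_that("titration datasets have the requested layout", {
  cfg <- small_config(image_height_px = 64L, image_width_px = 64L,
                      cab_count_range = c(5L, 8L), min_separation_px = 0)
  d <- simulate_titration(cfg, c(0, 10, 100, 300, 1000, 20000),
                          fovs_per_concentration = 2, rng_seed = 11)
  expect_length(d, 12L)
  expect_identical(unique(sapply(d, `[[`, "concentration")),
                   c(0, 10, 100, 300, 1000, 20000))
  single <- simulate_titration(cfg, 100, fovs_per_concentration = 1, rng_seed = 1)
  expect_length(single, 1L)
})
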