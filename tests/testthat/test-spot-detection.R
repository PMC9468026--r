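test_that("Gaussian denoising preserves constants, offsets, and mass", {
  const <- matrix(7, 32, 32)
  expect_equal(denoise(const), const, tolerance = 1e-12)
  # linearity: constant offset passes through unchanged
  set.seed(1)
  m <- matrix(runif(32 * 32, 0, 100), 32, 32)
  expect_equal(denoise(m + 5), denoise(m) + 5, tolerance = 1e-9)
  # single bright pixel: blur conserves total mass away from the boundary
  spike <- matrix(0, 41, 41); spike[21, 21] <- 1000
  expect_equal(sum(denoise(spike)), 1000, tolerance = 1e-6)
  # matches a dense 2-D convolution oracle
  small <- matrix(runif(15 * 12, 0, 50), 15, 12)
  expect_equal(denoise(small, 0.8), blur_oracle(small, 0.8), tolerance = 1e-10)
  expect_error(denoise(matrix(numeric(0), 0, 0)), "empty")
})

test_that("background reconstruction removes flat and ramped illumination", {
  flat <- matrix(50, 64, 64)
  sub <- subtract_background(flat)
  expect_true(all(sub$subtracted == 0))
  # reconstruction never exceeds its mask, so the difference is never negative
  set.seed(2)
  noisy <- denoise(matrix(rpois(64 * 64, 100), 64, 64))
  s2 <- subtract_background(noisy)
  expect_true(all(s2$subtracted >= -1e-9))
  expect_true(all(s2$background <= noisy + 1e-9))
})

test_that("spots on an illumination ramp survive only after subtraction", {
  set.seed(5)
  h <- 256L; w <- 128L
  ramp <- matrix(rep(seq(0, 200, length.out = w), each = h), h, w)
  pts <- smcoloc:::.sample_positions(30, w - 20, h - 20, 8) + 10
  mean_img <- ramp + 100 +
    smcoloc:::.render_spots(h, w, pts[, 1], pts[, 2], rep(500, 30), 1.2)
  img <- matrix(rpois(length(mean_img), mean_img), h, w)
  stitched <- cbind(img, matrix(100L, h, w))
  det <- detect_spots(stitched, "capture")$spots
  hits <- sum(sapply(seq_len(30), function(i)
    any((det$x - pts[i, 1])^2 + (det$y - pts[i, 2])^2 < 1)))
  expect_identical(nrow(det), 30L)
  expect_identical(hits, 30L)
  # skipping background subtraction leaves ramp-driven maxima in the selection
  no_sub <- smcoloc:::.select_maxima(transform_intensity(denoise(img)))
  expect_false(nrow(no_sub) == 30L)
})

test_that("asinh transform is monotone with the closed-form anchor", {
  expect_identical(transform_intensity(matrix(0, 2, 2), scale = 1),
                   matrix(0, 2, 2))
  expect_equal(transform_intensity(matrix(1, 1, 1), scale = 1)[1, 1],
               log(1 + sqrt(2)), tolerance = 1e-12)
  set.seed(3)
  v <- sort(runif(100, 0, 1e4))
  tr <- transform_intensity(matrix(v, 1), scale = 17)
  expect_true(all(diff(as.vector(tr)) > 0))
})

test_that("maxima selection honors the median + 1.2 sd threshold exactly", {
  base <- c(rep(1, 60), rep(2.2, 60))
  place <- function(vals) {
    # isolated single-pixel bumps on a zero background, 4 px apart
    m <- matrix(0, 50, 50)
    k <- seq_along(vals) - 1
    idx <- cbind(4L * (k %% 11L) + 2L, 4L * (k %/% 11L) + 2L)
    m[idx] <- vals
    m
  }
  thr_gap <- function(mult) {
    f <- function(t) {
      v <- c(base, t)
      (median(v) + mult * sd(v)) - t
    }
    uniroot(f, c(0.1, 1000))$root
  }
  t_below <- thr_gap(1.19)   # sits at median + 1.19 sd of the population
  t_above <- thr_gap(1.21)
  sel_below <- smcoloc:::.select_maxima(place(c(base, t_below)), 1.2)
  sel_above <- smcoloc:::.select_maxima(place(c(base, t_above)), 1.2)
  expect_false(any(abs(sel_below$intensity - t_below) < 1e-9))
  expect_true(any(abs(sel_above$intensity - t_above) < 1e-9))
})

test_that("detection is exact on well-separated bright spots", {
  cfg <- small_config()
  exact <- 0L; errs <- c()
  for (i in 1:25) {
    sim <- simulate_fov(cfg, 404, rng_seed = 7000 + i)
    vis <- sim$truth$cab[sim$truth$cab$dyes > 0, ]
    det <- detect_spots(sim$frame, "capture")$spots
    if (nrow(det) == nrow(vis)) exact <- exact + 1L
    d <- sqrt(outer(vis$x, det$x, "-")^2 + outer(vis$y, det$y, "-")^2)
    errs <- c(errs, apply(d, 1, min))
  }
  expect_gte(exact, 24L)
  expect_lt(median(errs), 1)
})

test_that("plateaus count once, inputs are not mutated, thresholds are monotone", {
  # a 2x2 plateau of equal values is one spot at its centroid
  m <- matrix(0, 20, 40); m[10:11, 10:11] <- 5
  mx <- smcoloc:::.local_maxima_cpp(m)
  expect_length(mx$x, 1L)
  expect_equal(mx$x, 9.5); expect_equal(mx$y, 9.5)  # 0-based centroid
  # constant frame yields no spots
  expect_identical(nrow(detect_spots(matrix(3L, 64, 64), "capture")$spots), 0L)
  # input frame unchanged by detection
  sim <- simulate_fov(small_config(), 300, rng_seed = 77)
  before <- sim$frame$pixels + 0L
  invisible(detect_spots(sim$frame, "detection"))
  expect_identical(sim$frame$pixels, before)
  # raising the multiplier never increases the count
  n12 <- nrow(detect_spots(sim$frame, "capture", threshold_multiplier = 1.2)$spots)
  n20 <- nrow(detect_spots(sim$frame, "capture", threshold_multiplier = 2.0)$spots)
  expect_lte(n20, n12)
})

test_that("the quality filter keeps centered fields and drops skewed ones", {
  even <- spot_set(cbind(runif(100, 0, 127), runif(100, 0, 511)), "capture")
  expect_true(qc_filter(even, 512)$keep)
  top <- spot_set(cbind(runif(50, 0, 127), runif(50, 0, 100)), "capture")
  expect_false(qc_filter(top, 512)$keep)
  expect_false(qc_filter(spot_set(cbind(numeric(0), numeric(0)), "capture"), 512)$keep)
  # clean simulated fields are discarded at under 1%
  cfg <- small_config()
  kept <- sapply(1:30, function(i) {
    sim <- simulate_fov(cfg, 300, rng_seed = 8000 + i)
    qc_filter(detect_spots(sim$frame, "capture"), cfg$image_height_px)$keep
  })
  expect_identical(sum(!kept), 0L)
})
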