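test_that("the pixel-distance criterion is sharp at the boundary", {
  cab <- spot_set(cbind(10, 10), "capture")
  expect_identical(
    colocalize(cab, spot_set(cbind(11.4, 10), "detection"))$counts$coloc_count, 1L)
  expect_identical(
    colocalize(cab, spot_set(cbind(11.6, 10), "detection"))$counts$coloc_count, 0L)
  expect_identical(
    colocalize(cab, spot_set(cbind(numeric(0), numeric(0)), "detection"))$counts$coloc_count, 0L)
  expect_error(colocalize(cab, cab, radius_px = 0), "radius")
})

test_that("greedy one-to-one matching equals the all-pairs brute-force oracle", {
  set.seed(10)
  for (rep in 1:40) {
    C <- cbind(runif(20, 0, 15), runif(20, 0, 15))
    D <- cbind(runif(20, 0, 15), runif(20, 0, 15))
    got <- colocalize(spot_set(C, "capture"), spot_set(D, "detection"))$counts$coloc_count
    expect_identical(got, coloc_oracle(C, D, 1.5))
  }
})

test_that("pair counts respect monotonicity, symmetry, and the min bound", {
  set.seed(11)
  C <- cbind(runif(30, 0, 20), runif(30, 0, 20))
  D <- cbind(runif(25, 0, 20), runif(25, 0, 20))
  cs <- spot_set(C, "capture"); ds <- spot_set(D, "detection")
  n1 <- colocalize(cs, ds, radius_px = 1.0)$counts$coloc_count
  n2 <- colocalize(cs, ds, radius_px = 1.5)$counts$coloc_count
  n3 <- colocalize(cs, ds, radius_px = 3.0)$counts$coloc_count
  expect_true(n1 <= n2 && n2 <= n3)
  expect_lte(n3, min(nrow(C), nrow(D)))
  # swapping roles with the inverse transform gives the same count
  tt <- sim_config()$true_transform
  a <- colocalize(cs, ds, tt)$counts$coloc_count
  b <- colocalize(spot_set(D, "capture"), spot_set(C, "detection"),
                  invert_transform(tt))$counts$coloc_count
  expect_identical(a, b)
})

test_that("bound pairs from the generator are recovered at the 1.5 px criterion", {
  cfg <- small_config(nonspecific_dab_per_fov = 30, cab_count_range = c(150L, 150L),
                      min_separation_px = 5)
  recovered <- 0L; bound <- 0L; false_pairs <- 0L; nonspec <- 0L
  for (i in 1:30) {
    tr <- simulate_fov(cfg, 2000, rng_seed = 1200 + i)$truth
    cab <- spot_set(as.matrix(tr$cab[, c("x", "y")]), "capture")
    dab_xy <- rbind(as.matrix(tr$dab_specific[, c("x", "y")]),
                    as.matrix(tr$dab_nonspecific[, c("x", "y")]))
    res <- colocalize(cab, spot_set(dab_xy, "detection"), cfg$true_transform)
    spec_idx <- seq_len(nrow(tr$dab_specific))
    recovered <- recovered + sum(res$pairs$dab_idx %in% spec_idx &
                                 res$pairs$cab_idx == tr$dab_specific$pair_id[
                                   match(res$pairs$dab_idx, spec_idx)])
    bound <- bound + nrow(tr$dab_specific)
    false_pairs <- false_pairs + sum(!(res$pairs$dab_idx %in% spec_idx))
    nonspec <- nonspec + nrow(tr$dab_nonspecific)
  }
  expect_gte(recovered / bound, 0.99)
  # non-specific dAbs pair at about the analytic Poisson-coverage rate
  half_area_um2 <- (cfg$image_height_px * cfg$pixel_size_nm / 1000) *
    (cfg$image_width_px / 2 * cfg$pixel_size_nm / 1000)
  density <- 150 / half_area_um2
  p_false <- analytic_false_rate(density, 1.5 * cfg$pixel_size_nm) / 100
  se <- sqrt(p_false * (1 - p_false) / nonspec)
  expect_lt(abs(false_pairs / nonspec - p_false), 3 * se + 0.01)
})

test_that("normalization fills ratios and flags empty capture fields", {
  counts <- data.frame(cab_count = c(200L, 200L, 0L),
                       dab_count = c(80L, 80L, 10L),
                       coloc_count = c(0L, 50L, 0L))
  n <- normalize_counts(counts)
  expect_equal(n$normalized_coloc[1:2], c(0, 0.25))
  expect_equal(n$normalized_single[1:2], c(0.4, 0.4))
  expect_true(is.na(n$normalized_coloc[3]))
  expect_identical(n$valid, c(TRUE, TRUE, FALSE))
})

test_that("aggregation reports sample CVs and normalization shrinks them", {
  same <- normalize_counts(data.frame(cab_count = rep(100L, 3),
                                      dab_count = rep(40L, 3),
                                      coloc_count = rep(20L, 3)))
  agg0 <- aggregate_counts(same)
  expect_true(all(agg0$cv == 0))
  two <- normalize_counts(data.frame(cab_count = c(200L, 200L),
                                     dab_count = c(80L, 80L),
                                     coloc_count = c(90L, 110L)))
  row <- aggregate_counts(two)
  cc <- row[row$statistic == "coloc_count", ]
  expect_equal(cc$mean, 100)
  expect_equal(cc$sd, sd(c(90, 110)))          # n - 1 denominator
  expect_equal(cc$cv, 0.1414214, tolerance = 1e-6)
  # heterogeneous capture loading: normalized colocalized counts vary less
  set.seed(12)
  cab <- round(runif(40, 100, 300))
  dat <- normalize_counts(data.frame(
    cab_count = cab,
    dab_count = rpois(40, 0.4 * cab),
    coloc_count = rpois(40, 0.25 * cab)))
  agg <- aggregate_counts(dat)
  expect_lt(agg$cv[agg$statistic == "normalized_coloc"],
            agg$cv[agg$statistic == "dab_count"])
  expect_error(aggregate_counts(same[0, ]), "at least 2")
})
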