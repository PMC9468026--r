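# Small simulation config used across tests: quarter-size stitched frames so
# the suite stays fast, bright spots (every visible spot SNR >= 10 over the
# sqrt(100) shot-noise floor), and well-separated placements.
small_config <- function(...) {
  defaults <- list(image_height_px = 256L, image_width_px = 256L,
                   cab_count_range = c(40L, 60L), min_separation_px = 8,
                   nonspecific_dab_per_fov = 0, spot_amplitude = 150)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Dense 2-D Gaussian convolution oracle (direct double loop, reflect
# boundary), independent of the package's separable implementation.
blur_oracle <- function(m, sigma) {
  r <- ceiling(4 * sigma)
  k <- outer(-r:r, -r:r, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  k <- k / sum(k)
  reflect <- function(i, n) {
    i <- (i %% (2 * n)); i <- ifelse(i < 0, i + 2 * n, i)
    ifelse(i < n, i, 2 * n - 1 - i)
  }
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- reflect(i - 1 + di, nrow(m)) + 1
      jj <- reflect(j - 1 + dj, ncol(m)) + 1
      acc <- acc + k[di + r + 1, dj + r + 1] * m[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# Brute-force greedy one-to-one pairing oracle: enumerate all pairs within
# the radius, sort by (distance, i, j), accept greedily.
coloc_oracle <- function(C, D, radius) {
  cand <- NULL
  for (i in seq_len(nrow(C))) for (j in seq_len(nrow(D))) {
    dij <- sqrt(sum((C[i, ] - D[j, ])^2))
    if (dij <= radius) cand <- rbind(cand, c(i, j, dij))
  }
  if (is.null(cand)) return(0L)
  cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  used_i <- used_j <- integer(0)
  n <- 0L
  for (k in seq_len(nrow(cand))) {
    if (!(cand[k, 1] %in% used_i) && !(cand[k, 2] %in% used_j)) {
      used_i <- c(used_i, cand[k, 1]); used_j <- c(used_j, cand[k, 2])
      n <- n + 1L
    }
  }
  n
}

# O(n^2) pairwise-comparison AUC oracle (Mann-Whitney statistic with 1/2 for
# ties).
auc_oracle <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Unpenalized logistic log-loss and its analytic gradient, for checking
# first-order optimality of the fitted coefficients.
logloss <- function(w, c0, x, y) {
  eta <- w * x + c0
  sum(log(1 + exp(-ifelse(y == 1, 1, -1) * eta)))
}
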