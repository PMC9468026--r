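#' Simulation configuration for synthetic two-color single-molecule frames
#'
#' Collects the generative truth for one virtual assay: geometry of the
#' stitched frame (capture channel in the left half, detection channel in the
#' right half), the point-spread function, capture-antibody surface loading,
#' the Langmuir occupancy parameters used to decide which capture antibodies
#' carry a bound detection antibody, non-specific detection-antibody
#' background, Poisson dye labeling, the camera noise model, and the true
#' inter-channel misregistration.
#'
#' @param image_height_px,image_width_px Stitched frame size in pixels; the
#'   width must be even (two half-width channels). Defaults 512 x 512.
#' @param pixel_size_nm Physical pixel size (nm per px), default 100.
#' @param psf_sigma_px Gaussian PSF standard deviation in px, default 1.2.
#' @param cab_count_range Integer range `c(min, max)` of capture antibodies
#'   per field of view, default `c(150, 300)`.
#' @param kd Equilibrium dissociation constant of the sandwich (pM),
#'   default 404.
#' @param bmax_fraction Fraction of capture antibodies occupied at
#'   saturation (0-1), default 0.65; values below 1 emulate incompletely
#'   active or incompletely labeled antibody.
#' @param nonspecific_dab_per_fov Expected count of non-specifically adsorbed
#'   detection antibodies per field of view (Poisson mean), default 40.
#' @param dol_cab,dol_dab Mean dyes per antibody (degree of labeling,
#'   Poisson), default 4 for both channels.
#' @param spot_amplitude Peak signal per dye molecule, in camera counts,
#'   default 60.
#' @param background_level Mean background in counts, default 100; shot noise
#'   is Poisson on signal plus background.
#' @param read_noise_sd Gaussian read noise standard deviation in counts,
#'   default 2.
#' @param jitter_sd_px Standard deviation of the radial displacement of a
#'   bound detection antibody from its capture antibody (px), default 0.5;
#'   accounts for antibody size and localization error and keeps true pairs
#'   within the 1.5 px colocalization criterion with probability > 0.999.
#' @param min_separation_px Minimum pairwise distance enforced between
#'   capture antibodies (px); 0 (default) places them as a binomial point
#'   process.
#' @param true_transform `affine2d` mapping detection-channel coordinates to
#'   the capture frame; default is a small near-identity misregistration.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(image_height_px = 512L, image_width_px = 512L,
                       pixel_size_nm = 100, psf_sigma_px = 1.2,
                       cab_count_range = c(150L, 300L),
                       kd = 404, bmax_fraction = 0.65,
                       nonspecific_dab_per_fov = 40,
                       dol_cab = 4, dol_dab = 4,
                       spot_amplitude = 60,
                       background_level = 100, read_noise_sd = 2,
                       jitter_sd_px = 0.5, min_separation_px = 0,
                       true_transform = NULL) {
  if (is.null(true_transform)) {
    th <- 0.1 * pi / 180           # 0.1 degree rotation
    m <- rbind(c(cos(th) * 1.001, -sin(th), 1.5),
               c(sin(th),  cos(th) * 1.001, -1.0),
               c(0, 0, 1))
    true_transform <- affine2d(m)
  }
  cfg <- list(image_height_px = as.integer(image_height_px),
              image_width_px = as.integer(image_width_px),
              pixel_size_nm = pixel_size_nm, psf_sigma_px = psf_sigma_px,
              cab_count_range = as.integer(cab_count_range),
              kd = kd, bmax_fraction = bmax_fraction,
              nonspecific_dab_per_fov = nonspecific_dab_per_fov,
              dol_cab = dol_cab, dol_dab = dol_dab,
              spot_amplitude = spot_amplitude,
              background_level = background_level,
              read_noise_sd = read_noise_sd,
              jitter_sd_px = jitter_sd_px,
              min_separation_px = min_separation_px,
              true_transform = true_transform)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (image_height_px < 8L || image_width_px < 8L || image_width_px %% 2L != 0L)
      stop("frame must be at least 8 px on a side with even width")
    area <- image_height_px * (image_width_px / 2)
    if (length(cab_count_range) != 2L || any(cab_count_range < 0) ||
        cab_count_range[1] > cab_count_range[2] || cab_count_range[2] > area)
      stop("cab_count_range must be an ordered pair within [0, half-image area]")
    if (kd <= 0) stop("kd must be positive")
    if (bmax_fraction < 0 || bmax_fraction > 1)
      stop("bmax_fraction must be in [0, 1]")
    if (nonspecific_dab_per_fov < 0 || dol_cab < 0 || dol_dab < 0 ||
        spot_amplitude < 0 || background_level < 0 || read_noise_sd < 0 ||
        jitter_sd_px < 0 || min_separation_px < 0)
      stop("rates, labeling, amplitude and noise parameters must be >= 0")
    if (!inherits(true_transform, "affine2d")) stop("true_transform must be an affine2d")
  })
  invisible(cfg)
}

#' Sample per-antibody dye counts
#'
#' Degree of labeling is modeled as Poisson: the probability of an antibody
#' carrying `x` dyes is `exp(-dol) * dol^x / x!`, so at a mean labeling of 3
#' or more dyes the chance of a dark (zero-dye) antibody is below `exp(-3)`.
#'
#' @param dol Mean dyes per antibody (>= 0).
#' @param n Number of antibodies (>= 1).
#' @param rng_seed Optional integer seed.
#' @return Integer vector of length `n`.
#' @export
sample_dye_counts <- function(dol, n, rng_seed = NULL) {
  if (dol < 0) stop("dol must be >= 0")
  if (n < 1) stop("n must be >= 1")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  rpois(n, dol)
}

# uniform points in [0, w-1] x [0, h-1]; optional minimum separation by
# dart throwing
.sample_positions <- function(n, width, height, min_sep = 0) {
  if (n == 0L)
    return(cbind(x = numeric(0), y = numeric(0)))
  if (min_sep <= 0)
    return(cbind(x = runif(n, 0, width - 1), y = runif(n, 0, height - 1)))
  xs <- numeric(n); ys <- numeric(n); got <- 0L; tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > 200L * n)
      stop("could not place points at the requested minimum separation")
    x <- runif(1, 0, width - 1); y <- runif(1, 0, height - 1)
    if (got == 0L || all((xs[seq_len(got)] - x)^2 + (ys[seq_len(got)] - y)^2 >= min_sep^2)) {
      got <- got + 1L; xs[got] <- x; ys[got] <- y
    }
  }
  cbind(x = xs, y = ys)
}

# render isotropic Gaussian spots (peak amplitude `amp`) onto a mean image
.render_spots <- function(height, width, x, y, amp, sigma) {
  img <- matrix(0, height, width)
  if (length(x) == 0L) return(img)
  r <- ceiling(4 * sigma)
  for (k in seq_along(x)) {
    if (amp[k] <= 0) next
    cols <- max(0, floor(x[k]) - r):min(width - 1, ceiling(x[k]) + r)
    rows <- max(0, floor(y[k]) - r):min(height - 1, ceiling(y[k]) + r)
    if (length(cols) == 0L || length(rows) == 0L) next
    gy <- exp(-(rows - y[k])^2 / (2 * sigma^2))
    gx <- exp(-(cols - x[k])^2 / (2 * sigma^2))
    img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] + amp[k] * (gy %o% gx)
  }
  img
}

# camera model: Poisson shot noise on the mean image, additive Gaussian read
# noise, quantized to 16-bit counts
.camera_readout <- function(mean_img, read_noise_sd) {
  n <- length(mean_img)
  counts <- rpois(n, lambda = as.vector(mean_img)) + rnorm(n, 0, read_noise_sd)
  m <- matrix(pmin(pmax(round(counts), 0), 65535), nrow(mean_img), ncol(mean_img))
  storage.mode(m) <- "integer"
  m
}

.new_frame <- function(pixels, fov_id) {
  structure(list(pixels = pixels, fov_id = fov_id), class = "image_frame")
}

#' Simulate one two-color field of view with ground truth
#'
#' Capture antibodies are placed uniformly in the left (capture) half-image;
#' each is occupied by a detection antibody with the Langmuir probability
#' `bmax_fraction * c / (kd + c)` at analyte concentration `c`. A bound
#' detection antibody sits at its capture antibody's position plus a small
#' radial jitter in the capture frame and is rendered in the right
#' (detection) half at the coordinates obtained by pushing that position
#' through the inverse of the true detection-to-capture transform.
#' Non-specific detection antibodies (Poisson count, uniform positions) are
#' added, every antibody draws a Poisson dye count, and spots are rendered as
#' Gaussian PSFs under Poisson shot noise plus Gaussian read noise.
#'
#' @param config A [sim_config()].
#' @param concentration Analyte concentration in pM (>= 0).
#' @param rng_seed Optional integer seed; identical seeds give bit-identical
#'   frames and ground truth.
#' @param fov_id Identifier stored on the frame.
#' @return List with `frame` (an `image_frame`: integer pixel matrix,
#'   `fov_id`) and `truth`, a list of data frames `cab` (x, y, dyes, bound),
#'   `dab_specific` (x, y in the detection half frame, dyes, pair_id indexing
#'   `cab`) and `dab_nonspecific` (x, y, dyes).
#' @export
simulate_fov <- function(config, concentration, rng_seed = NULL, fov_id = "fov1") {
  stopifnot(inherits(config, "sim_config"))
  if (concentration < 0) stop("concentration must be >= 0")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  h <- config$image_height_px
  wh <- config$image_width_px %/% 2L

  n_cab <- if (config$cab_count_range[1] == config$cab_count_range[2])
    config$cab_count_range[1]
  else sample(config$cab_count_range[1]:config$cab_count_range[2], 1L)
  cab <- .sample_positions(n_cab, wh, h, config$min_separation_px)
  p_bound <- config$bmax_fraction * concentration / (config$kd + concentration)
  bound <- if (n_cab > 0L) rbinom(n_cab, 1L, p_bound) == 1L else logical(0)
  cab_dyes <- if (n_cab > 0L) rpois(n_cab, config$dol_cab) else integer(0)

  # specific dAbs: jitter is radial (per-axis sd = jitter_sd / sqrt(2))
  idx <- which(bound)
  ax_sd <- config$jitter_sd_px / sqrt(2)
  spec_cap <- cbind(x = cab[idx, 1] + rnorm(length(idx), 0, ax_sd),
                    y = cab[idx, 2] + rnorm(length(idx), 0, ax_sd))
  spec_det <- apply_transform(invert_transform(config$true_transform), spec_cap)

  n_ns <- rpois(1, config$nonspecific_dab_per_fov)
  ns <- .sample_positions(n_ns, wh, h)
  dab_dyes <- rpois(length(idx) + n_ns, config$dol_dab)

  amp <- config$spot_amplitude
  left <- .render_spots(h, wh, cab[, 1], cab[, 2], cab_dyes * amp, config$psf_sigma_px)
  right <- .render_spots(h, wh, c(spec_det[, 1], ns[, 1]), c(spec_det[, 2], ns[, 2]),
                         dab_dyes * amp, config$psf_sigma_px)
  mean_img <- cbind(left, right) + config$background_level
  pixels <- .camera_readout(mean_img, config$read_noise_sd)

  truth <- list(
    cab = data.frame(x = cab[, 1], y = cab[, 2], dyes = cab_dyes, bound = bound),
    dab_specific = data.frame(x = spec_det[, 1], y = spec_det[, 2],
                              dyes = dab_dyes[seq_along(idx)], pair_id = idx),
    dab_nonspecific = data.frame(x = ns[, 1], y = ns[, 2],
                                 dyes = dab_dyes[length(idx) + seq_len(n_ns)]))
  list(frame = .new_frame(pixels, fov_id), truth = truth)
}

#' Simulate fiducial bead frames for channel registration
#'
#' Beads appear in both half-images: capture-frame positions are uniform, and
#' each detection-frame position is the capture position pushed through the
#' inverse of `true_transform` plus per-axis Gaussian localization jitter.
#'
#' @param true_transform `affine2d`, detection-to-capture map to emulate.
#' @param n_frames Number of bead frames (>= 1), default 5.
#' @param beads_per_frame Beads per frame (>= 3; an affine needs three
#'   non-collinear points), default 50.
#' @param jitter_sd_px Per-axis localization jitter (px), default 0.
#' @param rng_seed Optional integer seed.
#' @param image_height_px,image_width_px Stitched geometry, defaults 512.
#' @param bead_amplitude Peak bead brightness in counts, default 2000.
#' @param background_level,read_noise_sd,psf_sigma_px Camera/PSF model as in
#'   [sim_config()].
#' @return List of per-frame lists: `frame` (stitched `image_frame`),
#'   `capture_xy`, `detection_xy` (exact paired ground-truth coordinates).
#' @export
simulate_bead_frames <- function(true_transform, n_frames = 5L,
                                 beads_per_frame = 50L, jitter_sd_px = 0,
                                 rng_seed = NULL,
                                 image_height_px = 512L, image_width_px = 512L,
                                 bead_amplitude = 2000,
                                 background_level = 100, read_noise_sd = 2,
                                 psf_sigma_px = 1.2) {
  stopifnot(inherits(true_transform, "affine2d"))
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (beads_per_frame < 3L)
    stop("beads_per_frame must be >= 3 (affine estimation needs 3 non-collinear points)")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  h <- image_height_px; wh <- image_width_px %/% 2L
  Tinv <- invert_transform(true_transform)
  margin <- 8
  lapply(seq_len(n_frames), function(f) {
    cap <- cbind(x = runif(beads_per_frame, margin, wh - 1 - margin),
                 y = runif(beads_per_frame, margin, h - 1 - margin))
    det <- apply_transform(Tinv, cap) +
      matrix(rnorm(2 * beads_per_frame, 0, jitter_sd_px), ncol = 2)
    colnames(det) <- c("x", "y")
    left <- .render_spots(h, wh, cap[, 1], cap[, 2],
                          rep(bead_amplitude, beads_per_frame), psf_sigma_px)
    right <- .render_spots(h, wh, det[, 1], det[, 2],
                           rep(bead_amplitude, beads_per_frame), psf_sigma_px)
    pixels <- .camera_readout(cbind(left, right) + background_level, read_noise_sd)
    list(frame = .new_frame(pixels, paste0("beads", f)),
         capture_xy = cap, detection_xy = det)
  })
}

#' Simulate a full titration dataset
#'
#' One call per field of view of [simulate_fov()], across a concentration
#' ladder, with per-FOV seeds derived deterministically from `rng_seed`.
#'
#' @param config A [sim_config()].
#' @param concentrations Non-negative concentrations in pM; default ladder
#'   `c(0, 10, 100, 300, 1000, 20000)`.
#' @param fovs_per_concentration Fields of view per concentration (>= 1),
#'   default 16.
#' @param rng_seed Optional integer seed.
#' @return List of entries `concentration`, `frame`, `truth`, `fov_id`.
#' @export
simulate_titration <- function(config,
                               concentrations = c(0, 10, 100, 300, 1000, 20000),
                               fovs_per_concentration = 16L, rng_seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(concentrations) == 0L) stop("concentration list must be non-empty")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (fovs_per_concentration < 1L) stop("fovs_per_concentration must be >= 1")
  if (is.null(rng_seed)) rng_seed <- sample.int(1e6, 1)
  grid <- expand.grid(fov = seq_len(fovs_per_concentration),
                      conc = concentrations)
  lapply(seq_len(nrow(grid)), function(i) {
    seed_i <- (rng_seed + 7919 * i) %% 2147483647
    fid <- sprintf("c%g_f%02d", grid$conc[i], grid$fov[i])
    sim <- simulate_fov(config, grid$conc[i], rng_seed = seed_i, fov_id = fid)
    list(concentration = grid$conc[i], frame = sim$frame, truth = sim$truth,
         fov_id = fid)
  })
}
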